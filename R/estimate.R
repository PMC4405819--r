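# FOCE-I estimation: empirical-Bayes eta modes by a vectorized
# safeguarded Newton search, Laplace-type objective with the interaction
# convention (residual variance evaluated at the conditional prediction),
# quasi-Newton outer optimization on transformed parameters, and RSE from
# a numerically differentiated Hessian.

candidate_covariates <- c("cyp2b6_18", "cyp2b6_6", "weight", "sex", "age",
                          "cyp2a6_9", "cyp2a6_17", "abcb1_1236",
                          "regimen", "cns")

genotype_reference <- c(cyp2b6_18 = "TT", cyp2b6_6 = "GT",
                        cyp2a6_9 = "GG", cyp2a6_17 = "GG",
                        abcb1_1236 = "CC")

#' Model specification for estimation
#'
#' Declares which covariates enter the clearance model, the structural
#' constants, and the centering values for continuous covariates.
#' Genotype covariates add one fractional-effect parameter per
#' non-reference level observed in the data (so a three-level genotype
#' contributes 2 degrees of freedom); binary and continuous covariates
#' add one.
#'
#' @param covariates character vector, a subset of
#'   `c("cyp2b6_18","cyp2b6_6","weight","sex","age","cyp2a6_9",
#'   "cyp2a6_17","abcb1_1236","regimen","cns")`.
#' @param v,ka fixed structural constants (V/F in L, ka in 1/h).
#' @param wt_center,age_center centering values; `NULL` means the dataset
#'   median at fit time.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(), v = 150, ka = 0.18,
                       wt_center = NULL, age_center = NULL) {
  bad <- setdiff(covariates, candidate_covariates)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(v > 0, ka > 0)
  structure(list(covariates = unique(covariates), v = v, ka = ka,
                 wt_center = wt_center, age_center = age_center),
            class = "model_spec")
}

# Per-covariate parameter labels for a given dataset: genotype covariates
# get one parameter per non-reference level present; binary/continuous one.
cov_par_info <- function(spec, subjects) {
  info <- list()
  for (nm in spec$covariates) {
    if (nm %in% names(genotype_levels)) {
      present <- intersect(genotype_levels[[nm]], unique(subjects[[nm]]))
      lev <- setdiff(present, genotype_reference[[nm]])
      if (length(lev) == 0) next  # covariate constant in these data
      info[[nm]] <- list(type = "genotype", levels = lev)
    } else if (nm %in% c("weight", "age")) {
      info[[nm]] <- list(type = "continuous")
    } else {
      info[[nm]] <- list(type = "binary")
    }
  }
  info
}

cov_df <- function(spec, subjects) {
  sum(vapply(cov_par_info(spec, subjects),
             function(i) if (i$type == "genotype") length(i$levels) else 1L,
             integer(1)))
}

# Build the numeric machinery shared by ofv/fit: observation arrays, the
# per-subject covariate design matrix (one column per fractional-effect
# parameter), and the resolved centering values.
build_context <- function(ds, spec) {
  validate_pk_dataset(ds)
  s <- ds$subjects
  o <- ds$observations
  if (nrow(o) == 0) stop("dataset has no observations", call. = FALSE)
  if (!all(s$id %in% o$id))
    stop("every subject needs at least one observation for estimation",
         call. = FALSE)
  wt_center <- spec$wt_center %||% stats::median(s$weight)
  age_center <- spec$age_center %||% stats::median(s$age)
  info <- cov_par_info(spec, s)
  cols <- list(); labels <- character()
  for (nm in names(info)) {
    i <- info[[nm]]
    if (i$type == "genotype") {
      for (lev in i$levels) {
        cols[[length(cols) + 1L]] <- as.numeric(s[[nm]] == lev)
        labels <- c(labels, paste0(nm, ".", lev))
      }
    } else if (i$type == "continuous") {
      cols[[length(cols) + 1L]] <- switch(nm,
        weight = s$weight - wt_center, age = s$age - age_center)
      labels <- c(labels, nm)
    } else {
      cols[[length(cols) + 1L]] <- switch(nm,
        sex = as.numeric(s$sex == "female"),
        regimen = as.numeric(s$regimen == "ART_plus_TB"),
        cns = as.numeric(s$cns == "yes"))
      labels <- c(labels, if (nm == "sex") "sex.female" else nm)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(s), 0)
  colnames(X) <- labels
  idx <- match(o$id, s$id)
  list(spec = spec, subjects = s, n_subj = nrow(s), n_obs = nrow(o),
       y = o$conc, time = o$time, dose = s$dose[idx], tau = s$tau[idx],
       subj = idx, X = X, labels = labels,
       wt_center = wt_center, age_center = age_center,
       continuous = names(info)[vapply(info, function(i)
         i$type == "continuous", logical(1))],
       info = info)
}

# Population clearances from the untransformed parameter list.
ctx_cl_pop <- function(ctx, cl_base, theta_vec) {
  mult <- rep(1, ctx$n_subj)
  for (k in seq_along(theta_vec))
    mult <- mult * (1 + theta_vec[k] * ctx$X[, k])
  cl_base * mult
}

# Conditional objective g_i(eta) per subject, vectorized over subjects:
# sum_j [ (y-f)^2/(sigma2 f^2) + log(sigma2 f^2) ] + eta^2/omega2.
ctx_g <- function(ctx, cl_pop, eta, omega2, sigma2) {
  cl <- cl_pop[ctx$subj] * exp(eta[ctx$subj])
  f <- conc_ss(ctx$time, ctx$dose, ctx$tau, cl, ctx$spec$v, ctx$spec$ka)
  vf <- sigma2 * f * f
  term <- (ctx$y - f)^2 / vf + log(vf)
  term[!is.finite(term)] <- 1e10  # overflowed predictions: steer away
  as.numeric(rowsum(term, ctx$subj, reorder = TRUE)) + eta^2 / omega2
}

# Vectorized safeguarded Newton search for the conditional modes.
# Derivatives by central differences in eta (the objective is smooth);
# steps are clamped and backtracked so g never increases.
ctx_ebe <- function(ctx, cl_pop, omega2, sigma2, eta0 = NULL,
                    tol = 1e-9, maxit = 60L) {
  n <- ctx$n_subj
  eta <- eta0 %||% numeric(n)
  h <- 1e-4
  g0 <- ctx_g(ctx, cl_pop, eta, omega2, sigma2)
  for (it in seq_len(maxit)) {
    gp <- ctx_g(ctx, cl_pop, pmin(eta + h, 9), omega2, sigma2)
    gm <- ctx_g(ctx, cl_pop, pmax(eta - h, -9), omega2, sigma2)
    grad <- (gp - gm) / (2 * h)
    hess <- (gp - 2 * g0 + gm) / h^2
    hess_ok <- pmax(hess, 1e-4)
    step <- -grad / hess_ok
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 1), -1)
    for (bt in 1:8) {
      eta1 <- pmax(pmin(eta + step, 8), -8)
      g1 <- ctx_g(ctx, cl_pop, eta1, omega2, sigma2)
      worse <- g1 > g0 + 1e-12 * abs(g0)
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    moved <- abs(eta1 - eta)
    eta <- eta1
    g0 <- g1
    if (max(moved) < tol) break
  }
  gp <- ctx_g(ctx, cl_pop, pmin(eta + h, 9), omega2, sigma2)
  gm <- ctx_g(ctx, cl_pop, pmax(eta - h, -9), omega2, sigma2)
  curv <- (gp - 2 * g0 + gm) / h^2
  list(eta = eta, g = g0, curvature = curv)
}

ctx_ofv <- function(ctx, cl_pop, omega2, sigma2, eta0 = NULL) {
  if (any(!is.finite(cl_pop)) || any(cl_pop <= 0)) return(list(ofv = 1e10))
  sol <- ctx_ebe(ctx, cl_pop, omega2, sigma2, eta0 = eta0)
  if (any(sol$curvature <= 0) || any(!is.finite(sol$g)))
    return(list(ofv = 1e10, sol = sol))
  list(ofv = sum(sol$g + log(omega2) + log(sol$curvature)), sol = sol)
}

#' Empirical-Bayes estimates of the subject-level random effects
#'
#' For each subject, finds the conditional mode `eta_hat` minimizing
#' `g(eta) = sum_j [(y_j - f_j(eta))^2 / (sigma2 f_j(eta)^2) +
#' log(sigma2 f_j(eta)^2)] + eta^2/omega2` over `eta` in `[-8, 8]`,
#' together with the curvature `d2g/deta2` at the mode.
#'
#' @param ds a [pk_dataset()] with observations.
#' @param p an [efv_params()] object with `omega2 > 0` and `sigma2 > 0`.
#' @param spec optional [model_spec()]; defaults to structural constants
#'   taken from `p` with clearances computed by [individual_cl()].
#' @return data.frame with columns `id`, `eta`, `curvature`.
#' @export
ebe <- function(ds, p, spec = NULL) {
  stopifnot(p$omega2 > 0, p$sigma2 > 0)
  spec <- spec %||% model_spec(v = p$v, ka = p$ka,
                               wt_center = p$wt_center,
                               age_center = p$age_center)
  ctx <- build_context(ds, spec)
  cl_pop <- individual_cl(ctx$subjects, p)
  sol <- ctx_ebe(ctx, cl_pop, p$omega2, p$sigma2)
  data.frame(id = ctx$subjects$id, eta = sol$eta,
             curvature = sol$curvature, stringsAsFactors = FALSE)
}

#' FOCE-I objective function value
#'
#' The Laplace-type approximation to -2 log marginal likelihood with the
#' interaction convention, additive constants dropped consistently:
#' `ofv = sum_i [ g_i(eta_hat_i) + log(omega2) + log(d2g_i/deta2) ]`.
#' Only differences between nested models evaluated under this same
#' convention (delta-OFV) are interpretable; the full -2 log likelihood is
#' `ofv + n_obs*log(2*pi) - n_subj*log(2)`.
#'
#' @inheritParams ebe
#' @param spec a [model_spec()] naming the active covariates. Effects for
#'   covariates not active in `spec` but present in `p$theta` are ignored.
#' @return The objective function value (scalar).
#' @export
ofv_focei <- function(ds, p, spec = NULL) {
  stopifnot(p$omega2 > 0, p$sigma2 > 0)
  spec <- spec %||% model_spec(
    covariates = intersect(names(p$theta), candidate_covariates),
    v = p$v, ka = p$ka, wt_center = p$wt_center,
    age_center = p$age_center)
  ctx <- build_context(ds, spec)
  cl_pop <- individual_cl(ctx$subjects, p)
  res <- ctx_ofv(ctx, cl_pop, p$omega2, p$sigma2)
  res$ofv
}

#' Control settings for [fit_focei()]
#'
#' @param maxit maximum outer iterations.
#' @param reltol relative tolerance on the objective for the outer
#'   quasi-Newton optimizer.
#' @param restarts jittered restarts attempted if the first optimization
#'   fails to converge.
#' @param compute_rse whether to compute relative standard errors from
#'   the numerically differentiated Hessian (adds ~p^2 objective
#'   evaluations).
#' @return A list of class `focei_control`.
#' @export
focei_control <- function(maxit = 500L, reltol = 1e-10, restarts = 3L,
                          compute_rse = TRUE) {
  structure(list(maxit = maxit, reltol = reltol, restarts = restarts,
                 compute_rse = compute_rse), class = "focei_control")
}

# transformed vector <-> natural parameters -----------------------------

psi_pack <- function(cl_base, theta_vec, omega2, sigma2, ctx) {
  cont <- ctx$labels %in% ctx$continuous
  phi <- ifelse(cont, theta_vec, log1p(theta_vec))
  c(log(cl_base), phi, log(omega2), log(sigma2))
}

psi_unpack <- function(psi, ctx) {
  k <- length(ctx$labels)
  theta_vec <- numeric(k)
  if (k) {
    phi <- psi[1 + seq_len(k)]
    cont <- ctx$labels %in% ctx$continuous
    theta_vec <- ifelse(cont, phi, expm1(phi))
  }
  list(cl_base = exp(psi[1]), theta = theta_vec,
       omega2 = exp(psi[k + 2]), sigma2 = exp(psi[k + 3]))
}

params_from_ctx <- function(ctx, cl_base, theta_vec, omega2, sigma2) {
  theta <- list()
  for (nm in names(ctx$info)) {
    i <- ctx$info[[nm]]
    if (i$type == "genotype") {
      lab <- paste0(nm, ".", i$levels)
      theta[[nm]] <- stats::setNames(theta_vec[match(lab, ctx$labels)],
                                     i$levels)
    } else {
      lab <- if (nm == "sex") "sex.female" else nm
      theta[[nm]] <- unname(theta_vec[match(lab, ctx$labels)])
    }
  }
  efv_params(cl_base = cl_base, theta = theta,
             wt_center = ctx$wt_center, age_center = ctx$age_center,
             v = ctx$spec$v, ka = ctx$spec$ka,
             omega2 = omega2, sigma2 = sigma2)
}

default_init <- function(ctx) {
  # the interval-averaged concentration is dose/(cl*tau): invert each
  # subject's mean observed concentration to a crude clearance, then
  # regress its log on the covariate design for starting effects
  ybar <- as.numeric(rowsum(ctx$y, ctx$subj) /
                       tabulate(ctx$subj, ctx$n_subj))
  dose_s <- numeric(ctx$n_subj); dose_s[ctx$subj] <- ctx$dose
  tau_s <- numeric(ctx$n_subj); tau_s[ctx$subj] <- ctx$tau
  clhat <- pmin(pmax(dose_s / (tau_s * pmax(ybar, 1e-3)), 0.05), 100)
  k <- length(ctx$labels)
  theta <- numeric(k)
  cl0 <- stats::median(clhat)
  omega2 <- 0.3
  if (k > 0) {
    co <- tryCatch(stats::coef(stats::lm(log(clhat) ~ ctx$X)),
                   error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) {
      cl0 <- exp(co[1])
      b <- co[-1]
      cont <- ctx$labels %in% ctx$continuous
      theta <- ifelse(cont, b, pmax(expm1(b), -0.9))
      res <- log(clhat) - cbind(1, ctx$X) %*% co
      omega2 <- min(max(stats::var(as.numeric(res)), 0.02), 2)
    }
  }
  list(cl_base = min(max(cl0, 0.5), 50), theta = theta,
       omega2 = omega2, sigma2 = 0.1)
}

#' Fit the nonlinear mixed-effects model by FOCE-I
#'
#' Minimizes [ofv_focei()] over the fixed effects and variance
#' components. Positive parameters are optimized on the log scale and
#' categorical fractional effects as `log(1 + theta)` so the search space
#' is unconstrained; the outer optimizer is BFGS with numerical
#' gradients, with jittered restarts on failure. Empirical-Bayes modes
#' are warm-started between outer iterations.
#'
#' @param ds a [pk_dataset()] with observations.
#' @param spec a [model_spec()].
#' @param init optional [efv_params()] starting values.
#' @param control a [focei_control()] list.
#' @return Object of class `focei_fit`: `params` (an [efv_params()]),
#'   `ofv`, `estimates` (named natural-scale vector), `rse` (named
#'   vector, % or NA), `ebes` (data.frame id/eta/curvature), `converged`,
#'   `n_iter`, `df` (number of covariate-effect parameters), `labels`.
#' @export
fit_focei <- function(ds, spec = model_spec(), init = NULL,
                      control = focei_control()) {
  ctx <- build_context(ds, spec)
  k <- length(ctx$labels)
  st <- if (is.null(init)) default_init(ctx) else {
    th <- numeric(k)
    for (nm in names(ctx$info)) {
      i <- ctx$info[[nm]]
      if (i$type == "genotype") {
        v <- init$theta[[nm]]
        for (lev in i$levels)
          th[match(paste0(nm, ".", lev), ctx$labels)] <-
            if (!is.null(v) && lev %in% names(v)) v[[lev]] else 0
      } else {
        lab <- if (nm == "sex") "sex.female" else nm
        th[match(lab, ctx$labels)] <- init$theta[[nm]] %||% 0
      }
    }
    list(cl_base = init$cl_base, theta = th,
         omega2 = max(init$omega2, 1e-3), sigma2 = max(init$sigma2, 1e-3))
  }
  psi0 <- psi_pack(st$cl_base, st$theta, st$omega2, st$sigma2, ctx)

  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  obj <- function(psi) {
    if (any(!is.finite(psi)) || any(abs(psi) > 20)) return(1e10)
    pr <- psi_unpack(psi, ctx)
    cl_pop <- ctx_cl_pop(ctx, pr$cl_base, pr$theta)
    res <- ctx_ofv(ctx, cl_pop, pr$omega2, pr$sigma2, eta0 = warm$eta)
    if (!is.null(res$sol) && is.finite(res$ofv) && res$ofv < 1e9)
      warm$eta <- res$sol$eta
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }

  run1 <- function(psi_start) {
    warm$eta <- NULL
    stats::optim(psi_start, obj, method = "BFGS",
                 control = list(maxit = control$maxit,
                                reltol = control$reltol,
                                ndeps = rep(1e-5, length(psi_start))))
  }
  opt <- run1(psi0)
  attempt <- 0L
  while ((opt$convergence != 0 || opt$value >= 1e9) &&
         attempt < control$restarts) {
    attempt <- attempt + 1L
    jit <- with_seed(1000 + attempt,
                     psi0 + stats::rnorm(length(psi0), 0, 0.3))
    opt2 <- run1(jit)
    if (opt2$value < opt$value) opt <- opt2
  }

  pr <- psi_unpack(opt$par, ctx)
  cl_pop <- ctx_cl_pop(ctx, pr$cl_base, pr$theta)
  sol <- ctx_ebe(ctx, cl_pop, pr$omega2, pr$sigma2)
  params <- params_from_ctx(ctx, pr$cl_base, pr$theta, pr$omega2,
                            pr$sigma2)
  est <- c(cl_base = pr$cl_base,
           stats::setNames(pr$theta, ctx$labels),
           omega2 = pr$omega2, sigma2 = pr$sigma2)
  fit <- structure(list(
    params = params, ofv = opt$value, estimates = est,
    rse = rep(NA_real_, length(est)),
    ebes = data.frame(id = ctx$subjects$id, eta = sol$eta,
                      curvature = sol$curvature,
                      stringsAsFactors = FALSE),
    converged = opt$convergence == 0 && opt$value < 1e9,
    n_iter = unname(opt$counts["function"]),
    df = k, labels = ctx$labels, spec = spec), class = "focei_fit")
  names(fit$rse) <- names(est)
  if (control$compute_rse) fit$rse <- rse_focei(fit, ds)
  fit
}

#' Relative standard errors from the numerical Hessian
#'
#' Standard errors are taken from the inverse of the Hessian of `ofv/2`
#' at the optimum, differentiated numerically on the natural parameter
#' scale; `RSE = 100 * SE / |estimate|`. A non-positive-definite Hessian
#' (flat or ridged directions) yields `NA` entries with a warning rather
#' than being masked.
#'
#' @param fit a converged `focei_fit`.
#' @param ds the dataset the fit was obtained on.
#' @return Named vector of RSE percentages (NA where unavailable).
#' @export
rse_focei <- function(fit, ds) {
  ctx <- build_context(ds, fit$spec)
  est <- fit$estimates
  k <- length(ctx$labels)
  f <- function(x) {
    cl_base <- x[1]
    theta <- if (k) x[1 + seq_len(k)] else numeric(0)
    omega2 <- x[k + 2]; sigma2 <- x[k + 3]
    if (cl_base <= 0 || omega2 <= 0 || sigma2 <= 0) return(1e10)
    cl_pop <- ctx_cl_pop(ctx, cl_base, theta)
    ctx_ofv(ctx, cl_pop, omega2, sigma2)$ofv / 2
  }
  H <- try(fd_hessian(f, unname(est)), silent = TRUE)
  out <- rep(NA_real_, length(est))
  names(out) <- names(est)
  if (inherits(H, "try-error") || any(!is.finite(H))) {
    warning("Hessian could not be evaluated; RSE unavailable")
    return(out)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("Hessian not positive definite; RSE reported where the ",
            "corresponding variance is positive")
  }
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error")) {
    warning("singular Hessian; RSE unavailable")
    return(out)
  }
  d <- diag(V)
  ok <- is.finite(d) & d > 0 & abs(est) > 0
  out[ok] <- 100 * sqrt(d[ok]) / abs(est[ok])
  out
}

#' @export
print.focei_fit <- function(x, ...) {
  cat("<focei_fit> ", if (x$converged) "converged" else "NOT converged",
      "; OFV = ", format(x$ofv, digits = 8),
      "; ", x$n_iter, " objective evaluations\n", sep = "")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse, 1))
  print(tab)
  invisible(x)
}

#' Write a fit report mirroring a final-parameter table
#'
#' Plain-text table of estimates with RSE and fixed-flag columns, plus
#' the genotype-specific clearances implied by the fit, and a CSV of
#' empirical-Bayes estimates (ID, ETA, IPRED).
#'
#' @param fit a `focei_fit`.
#' @param ds the fitted dataset (for individual predictions).
#' @param path report file path; the EBE CSV is written next to it with
#'   suffix `_ebe.csv`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, ds, path) {
  p <- fit$params
  cl18 <- cl_by_cyp2b6_18(p)
  lines <- c(
    "Final population PK parameter estimates",
    sprintf("%-22s %12s %10s %6s", "parameter", "estimate", "RSE%",
            "fixed"),
    sprintf("%-22s %12.4g %10s %6s", "CL/F_TT (L/h)", cl18["TT"],
            fmt_rse(fit$rse["cl_base"]), "no"),
    if ("cyp2b6_18.TC" %in% fit$labels)
      sprintf("%-22s %12.4g %10s %6s", "CL/F_TC (L/h)", cl18["TC"],
              fmt_rse(fit$rse["cyp2b6_18.TC"]), "no"),
    if ("cyp2b6_18.CC" %in% fit$labels)
      sprintf("%-22s %12.4g %10s %6s", "CL/F_CC (L/h)", cl18["CC"],
              fmt_rse(fit$rse["cyp2b6_18.CC"]), "no"),
    sprintf("%-22s %12.4g %10s %6s", "V/F (L)", p$v, "-", "yes"),
    sprintf("%-22s %12.4g %10s %6s", "ka (1/h)", p$ka, "-", "yes"))
  for (lab in setdiff(fit$labels, c("cyp2b6_18.TC", "cyp2b6_18.CC"))) {
    est <- fit$estimates[lab]
    lines <- c(lines, sprintf("%-22s %11.3g%% %10s %6s",
                              paste0("effect ", lab), 100 * est,
                              fmt_rse(fit$rse[lab]), "no"))
  }
  lines <- c(lines,
    sprintf("%-22s %12.4g %10s %6s", "omega2 (IIV var)",
            p$omega2, fmt_rse(fit$rse["omega2"]), "no"),
    sprintf("%-22s %11.1f%% %10s %6s", "IIV (%CV)",
            100 * sqrt(p$omega2), "-", "no"),
    sprintf("%-22s %12.4g %10s %6s", "sigma2 (prop err var)",
            p$sigma2, fmt_rse(fit$rse["sigma2"]), "no"),
    sprintf("OFV %.6f  (converged: %s)", fit$ofv, fit$converged))
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  idx <- match(ds$observations$id, ds$subjects$id)
  eta <- fit$ebes$eta[match(ds$observations$id, fit$ebes$id)]
  ipred <- predict_conc(ds$subjects[idx, ], ds$observations$time,
                        p, eta = eta)
  utils::write.csv(data.frame(ID = ds$observations$id, ETA = eta,
                              IPRED = ipred),
                   sub("\\.[^.]+$", "_ebe.csv", path),
                   row.names = FALSE)
  invisible(path)
}

fmt_rse <- function(x) if (is.na(x)) "NA" else sprintf("(%.0f)", x)

# Central-difference Hessian with a relative step large enough that the
# objective differences dominate the inner-solver noise floor (generic
# fixed-step differentiators under-step the soft directions of a
# Laplace-type objective and can return spurious negative curvature).
fd_hessian <- function(f, x, rel_step = 1e-3) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 0.01)
  f0 <- f(x)
  H <- matrix(NA_real_, p, p)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    fp[i] <- f(x + ei); fm[i] <- f(x - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ei <- numeric(p); ei[i] <- h[i]
    ej <- numeric(p); ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
         f(x - ei - ej)) / (4 * h[i] * h[j])
  }
  H
}
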