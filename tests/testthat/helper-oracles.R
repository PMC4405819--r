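# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: the ODE oracle integrates the
# one-compartment system to steady state with deSolve, and the marginal
# likelihood oracle uses adaptive Gauss-Hermite quadrature centred by a
# base-R 1-D optimizer.

# Steady-state concentration by numerical integration of the absorption/
# disposition ODEs over >= 20 doses, read t hours after the last dose.
ode_conc_ss <- function(t, dose, tau, cl, v, ka, n_doses = NULL) {
  # enough doses that the remaining accumulation error is < 1e-7 relative
  if (is.null(n_doses))
    n_doses <- max(30, ceiling(16 / ((cl / v) * tau)) + 10)
  deriv <- function(time, y, parms) {
    list(c(-ka * y[1], ka * y[1] / v - (cl / v) * y[2]))
  }
  y <- c(gut = 0, conc = 0)
  for (d in seq_len(n_doses - 1)) {
    y["gut"] <- y["gut"] + dose
    sol <- deSolve::lsoda(y, c(0, tau), deriv, NULL,
                          rtol = 1e-10, atol = 1e-12)
    y <- c(gut = unname(sol[2, "gut"]), conc = unname(sol[2, "conc"]))
  }
  y["gut"] <- y["gut"] + dose
  sol <- deSolve::lsoda(y, c(0, t), deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(sol[2, "conc"])
}

# -2 log marginal likelihood (full constants) by 64-node adaptive
# Gauss-Hermite quadrature; the mode/scale for the adaptive shift come
# from stats::optimize + a finite-difference curvature, independent of
# the package's Newton solver.
agq_m2ll <- function(ds, p, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (i in seq_len(nrow(ds$subjects))) {
    s1 <- ds$subjects[i, , drop = FALSE]
    oo <- ds$observations[ds$observations$id == s1$id, , drop = FALSE]
    nlj <- function(eta) {
      f <- predict_conc(s1[rep(1, nrow(oo)), , drop = FALSE],
                        oo$time, p, eta = eta)
      -sum(stats::dnorm(oo$conc, f, sqrt(p$sigma2) * f, log = TRUE)) -
        stats::dnorm(eta, 0, sqrt(p$omega2), log = TRUE)
    }
    opt <- stats::optimize(nlj, c(-8, 8), tol = 1e-10)
    h <- 1e-4
    curv <- (nlj(opt$minimum + h) - 2 * opt$objective +
               nlj(opt$minimum - h)) / h^2
    sc <- sqrt(2 / max(curv, 1e-6)) * 1.5
    li <- sum(gh$w * exp(gh$x^2) *
                vapply(opt$minimum + sc * gh$x,
                       function(e) exp(-nlj(e)), numeric(1))) * sc
    total <- total - 2 * log(li)
  }
  total
}

# Convert the package's constant-dropped OFV to the full -2 log
# likelihood scale for comparison with agq_m2ll.
ofv_full_constants <- function(ofv, n_obs, n_subj) {
  ofv + n_obs * log(2 * pi) - n_subj * log(2)
}

# Single-covariate-type subjects for structural tests.
ref_subject <- function(n = 1, weight = 58, sex = "male", g18 = "TT",
                        g6 = "GT", dose = 600, tau = 24) {
  data.frame(id = sprintf("R%02d", seq_len(n)), sex = sex,
             weight = weight, age = 39, cyp2b6_6 = g6, cyp2b6_18 = g18,
             cyp2a6_9 = "GG", cyp2a6_17 = "GG", abcb1_1236 = "CC",
             regimen = "ART_only", cns = "no", dose = dose, tau = tau,
             stringsAsFactors = FALSE)
}

# A small fitted-cohort dataset at the reference parameter set.
recovery_cfg <- function(n = 200) {
  cohort_config(n_subjects = n, times = c(2, 13.5, 24))
}

final_spec <- function() {
  model_spec(c("cyp2b6_18", "cyp2b6_6", "weight", "sex"), wt_center = 58)
}
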