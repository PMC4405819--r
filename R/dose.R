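# Monte-Carlo dose optimization: simulate steady-state concentrations per
# covariate stratum over candidate daily doses and pick the dose that
# minimizes the proportion of individuals outside the 1-4 ug/ml
# therapeutic window.

#' Define a simulation stratum
#'
#' A stratum fixes the CYP2B6*18 and *6 genotypes, sex, and the weight
#' class used in the stratified dose table (below or above the 58 kg
#' boundary).
#'
#' @param cyp2b6_18 one of `"TT"`, `"TC"`, `"CC"`.
#' @param cyp2b6_6 one of `"GG"`, `"GT"`, `"TT"`.
#' @param sex `"male"` or `"female"`.
#' @param weight_class `"<58"` or `">58"` (kg).
#' @return List of class `pk_stratum`.
#' @export
stratum <- function(cyp2b6_18, cyp2b6_6, sex, weight_class) {
  if (!cyp2b6_18 %in% genotype_levels$cyp2b6_18 ||
      !cyp2b6_6 %in% genotype_levels$cyp2b6_6 ||
      !sex %in% c("male", "female") ||
      !weight_class %in% c("<58", ">58"))
    stop("invalid stratum definition", call. = FALSE)
  structure(list(cyp2b6_18 = cyp2b6_18, cyp2b6_6 = cyp2b6_6, sex = sex,
                 weight_class = weight_class), class = "pk_stratum")
}

# Draw n simulated individuals in a stratum and return their steady-state
# concentration per mg of daily dose (concentration is linear in dose, so
# one set of draws serves every candidate dose: common random numbers).
stratum_unit_conc <- function(st, p, n, cfg = cohort_config(),
                              include_residual = TRUE,
                              weight_boundary = 58) {
  wm <- if (st$sex == "female") cfg$weight_mean_female else
    cfg$weight_mean_male
  ws <- if (st$sex == "female") cfg$weight_sd_female else
    cfg$weight_sd_male
  lo <- if (st$weight_class == "<58") cfg$weight_range[1] else
    weight_boundary
  hi <- if (st$weight_class == "<58") weight_boundary else
    cfg$weight_range[2]
  weight <- rtruncnorm_inv(n, wm, ws, lo, hi)
  subjects <- data.frame(
    id = sprintf("sim%06d", seq_len(n)), sex = st$sex, weight = weight,
    age = 39, cyp2b6_6 = st$cyp2b6_6, cyp2b6_18 = st$cyp2b6_18,
    cyp2a6_9 = "GG", cyp2a6_17 = "GG", abcb1_1236 = "CC",
    regimen = "ART_only", cns = "no", dose = 1, tau = cfg$tau,
    stringsAsFactors = FALSE)
  eta <- stats::rnorm(n, 0, sqrt(p$omega2))
  time <- stats::runif(n, cfg$sampling_window[1], cfg$sampling_window[2])
  u <- predict_conc(subjects, time, p, eta = eta)
  if (include_residual && p$sigma2 > 0) {
    eps <- stats::rnorm(n, 0, sqrt(p$sigma2))
    for (tries in 1:100) {
      bad <- 1 + eps <= 0
      if (!any(bad)) break
      eps[bad] <- stats::rnorm(sum(bad), 0, sqrt(p$sigma2))
    }
    u <- u * (1 + eps)
  }
  u
}

window_props <- function(conc, window) {
  c(p_below = mean(conc < window[1]),
    p_within = mean(conc >= window[1] & conc <= window[2]),
    p_above = mean(conc > window[2]))
}

#' Therapeutic-window attainment at one dose
#'
#' Simulates `n` individuals in a stratum (weight from the sex-specific
#' truncated normal conditioned on the weight class, `eta` and `eps` per
#' the model, sampling time uniform 12-15 h post dose at steady state)
#' and returns the proportions of measured concentrations below, within
#' and above the therapeutic window.
#'
#' @param st a [stratum()].
#' @param dose daily dose (mg).
#' @param p an [efv_params()] object.
#' @param n individuals to simulate.
#' @param seed integer seed.
#' @param window therapeutic window in ug/ml (default `c(1, 4)`).
#' @param include_residual include the proportional residual (assay)
#'   error in simulated concentrations (the window refers to measured
#'   plasma levels); set `FALSE` to simulate error-free concentrations.
#' @param cfg a [cohort_config()] supplying weight distributions,
#'   sampling window and dosing interval.
#' @return One-row data.frame: `dose`, `p_below`, `p_within`, `p_above`.
#' @export
window_attainment <- function(st, dose, p, n = 1000, seed = NULL,
                              window = c(1, 4), include_residual = TRUE,
                              cfg = cohort_config()) {
  stopifnot(n >= 1, dose > 0)
  u <- with_seed(seed, stratum_unit_conc(st, p, n, cfg, include_residual))
  data.frame(dose = dose, t(window_props(dose * u, window)))
}

#' Optimal dose for a stratum
#'
#' Evaluates every candidate dose on common random numbers (one set of
#' simulated individuals, concentrations scaled linearly by dose) and
#' returns the dose minimizing the proportion outside the window; ties
#' are broken by the lowest dose.
#'
#' @inheritParams window_attainment
#' @param doses candidate daily doses (mg).
#' @return List of class `dose_recommendation`: `stratum`,
#'   `recommended_dose`, and `window` (a data.frame of attainment
#'   proportions per candidate dose).
#' @export
recommend_dose <- function(st, p, doses = seq(200, 800, by = 100),
                           n = 1000, seed = NULL, window = c(1, 4),
                           include_residual = TRUE,
                           cfg = cohort_config()) {
  if (length(doses) == 0) stop("candidate dose set is empty",
                               call. = FALSE)
  doses <- sort(doses)
  u <- with_seed(seed, stratum_unit_conc(st, p, n, cfg, include_residual))
  win <- do.call(rbind, lapply(doses, function(d)
    data.frame(dose = d, t(window_props(d * u, window)))))
  outside <- win$p_below + win$p_above
  best <- doses[which.min(outside)]  # which.min takes the first == lowest
  structure(list(stratum = st, recommended_dose = best, window = win),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  st <- x$stratum
  cat(sprintf("<dose_recommendation> *18 %s / *6 %s / %s / %s kg: %g mg/day\n",
              st$cyp2b6_18, st$cyp2b6_6, st$sex, st$weight_class,
              x$recommended_dose))
  print(x$window, row.names = FALSE)
  invisible(x)
}

#' Genotype-, sex- and weight-stratified dose table
#'
#' Runs [recommend_dose()] over all 3 x 3 x 2 x 2 = 36 strata
#' (CYP2B6*18 x CYP2B6*6 x sex x weight class) in the standard table
#' order: genotype pairs by rows (*18 TT, TC, CC; within each, *6 GG,
#' GT, TT), columns females then males, `<58` then `>58` kg.
#' Deterministic given `seed` (each stratum gets a sub-seed split from
#' it).
#'
#' @inheritParams recommend_dose
#' @param seed root seed.
#' @return data.frame with one row per stratum: `cyp2b6_18`,
#'   `cyp2b6_6`, `sex`, `weight_class`, `recommended_dose`, and the
#'   attainment proportions at the recommended dose. The full attainment
#'   curves are attached as attribute `"curves"` (tidy: stratum columns,
#'   dose, p_below, p_within, p_above).
#' @export
build_dose_table <- function(p, doses = seq(200, 800, by = 100),
                             n = 1000, seed = NULL, window = c(1, 4),
                             include_residual = TRUE,
                             cfg = cohort_config()) {
  grid <- expand.grid(weight_class = c("<58", ">58"),
                      sex = c("female", "male"),
                      cyp2b6_6 = c("GG", "GT", "TT"),
                      cyp2b6_18 = c("TT", "TC", "CC"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("cyp2b6_18", "cyp2b6_6", "sex", "weight_class")]
  seeds <- if (is.null(seed)) vector("list", nrow(grid)) else
    as.list(split_seed(seed, nrow(grid)))
  rows <- vector("list", nrow(grid))
  curves <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- stratum(grid$cyp2b6_18[i], grid$cyp2b6_6[i], grid$sex[i],
                  grid$weight_class[i])
    rec <- recommend_dose(st, p, doses, n, seed = seeds[[i]],
                          window = window,
                          include_residual = include_residual, cfg = cfg)
    at <- rec$window[rec$window$dose == rec$recommended_dose, ]
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       recommended_dose = rec$recommended_dose,
                       at[, c("p_below", "p_within", "p_above")])
    curves[[i]] <- cbind(grid[i, , drop = FALSE], rec$window,
                         row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- do.call(rbind, curves)
  out
}

#' Reshape a dose table into the stratified grid layout
#'
#' Rows are (*18, *6) genotype pairs; columns are sex x weight class,
#' females first.
#'
#' @param tab output of [build_dose_table()].
#' @return data.frame with columns `cyp2b6_18`, `cyp2b6_6`,
#'   `female_lt58`, `female_gt58`, `male_lt58`, `male_gt58` (mg/day).
#' @export
dose_table_wide <- function(tab) {
  key <- function(sex, wc) tab$recommended_dose[
    tab$sex == sex & tab$weight_class == wc][
      match(paste(u18u6$cyp2b6_18, u18u6$cyp2b6_6),
            paste(tab$cyp2b6_18[tab$sex == sex & tab$weight_class == wc],
                  tab$cyp2b6_6[tab$sex == sex & tab$weight_class == wc]))]
  u18u6 <- unique(tab[, c("cyp2b6_18", "cyp2b6_6")])
  data.frame(u18u6,
             female_lt58 = key("female", "<58"),
             female_gt58 = key("female", ">58"),
             male_lt58 = key("male", "<58"),
             male_gt58 = key("male", ">58"),
             row.names = NULL)
}

#' Reference stratified dose recommendations
#'
#' The dose grid reported with the final model (mg/day) for the 36
#' strata, in the same layout as [dose_table_wide()]. Useful for
#' comparing a freshly simulated table against the reference analysis;
#' cells can disagree where the reference grid is not monotone in the
#' implied clearance (see [compare_dose_tables()]).
#'
#' @return data.frame matching the [dose_table_wide()] layout.
#' @export
reference_dose_table <- function() {
  data.frame(
    cyp2b6_18 = rep(c("TT", "TC", "CC"), each = 3),
    cyp2b6_6 = rep(c("GG", "GT", "TT"), 3),
    female_lt58 = c(400, 200, 200, 400, 400, 200, 400, 200, 200),
    female_gt58 = c(400, 200, 200, 400, 200, 200, 600, 300, 200),
    male_lt58   = c(400, 200, 200, 400, 200, 200, 600, 300, 200),
    male_gt58   = c(400, 200, 200, 400, 200, 200, 600, 300, 200),
    stringsAsFactors = FALSE)
}

#' Compare a simulated dose table against the reference grid
#'
#' @param tab output of [build_dose_table()].
#' @return Long data.frame with the simulated and reference dose per
#'   stratum and an `agrees` flag.
#' @export
compare_dose_tables <- function(tab) {
  ref <- reference_dose_table()
  long <- do.call(rbind, lapply(
    c("female_lt58", "female_gt58", "male_lt58", "male_gt58"),
    function(col) {
      sex <- if (grepl("female", col)) "female" else "male"
      wc <- if (grepl("lt58", col)) "<58" else ">58"
      data.frame(cyp2b6_18 = ref$cyp2b6_18, cyp2b6_6 = ref$cyp2b6_6,
                 sex = sex, weight_class = wc,
                 reference_dose = ref[[col]], stringsAsFactors = FALSE)
    }))
  out <- merge(tab, long,
               by = c("cyp2b6_18", "cyp2b6_6", "sex", "weight_class"))
  out$agrees <- out$recommended_dose == out$reference_dose
  out
}
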