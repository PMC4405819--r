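# One-compartment oral-absorption model at steady state, and the
# multiplicative covariate model for apparent clearance.

#' Steady-state concentration of a one-compartment oral model
#'
#' Closed-form concentration `t` hours after the last of many repeated
#' oral doses (superposition solution):
#'
#'   C(t) = D*ka / (V*(ka-ke)) *
#'          [ exp(-ke*t)/(1-exp(-ke*tau)) - exp(-ka*t)/(1-exp(-ka*tau)) ]
#'
#' with `ke = cl/v`. Near the flip-flop degeneracy `ka == ke` the
#' analytic limit expression is used, evaluated at the midpoint rate
#' constant, so the function is continuous across the switch.
#' All arguments are recycled to a common length.
#'
#' @param t time after dose (h), in `(0, tau]`.
#' @param dose dose (mg).
#' @param tau dosing interval (h).
#' @param cl apparent clearance CL/F (L/h).
#' @param v apparent volume V/F (L).
#' @param ka absorption rate constant (1/h).
#' @return Concentration in ug/ml (mg/L).
#' @export
conc_ss <- function(t, dose, tau, cl, v = 150, ka = 0.18) {
  n <- max(length(t), length(dose), length(tau), length(cl),
           length(v), length(ka))
  t <- rep_len(t, n); dose <- rep_len(dose, n); tau <- rep_len(tau, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  if (any(t <= 0 | t > tau))
    stop("t must lie in (0, tau]", call. = FALSE)
  if (any(dose <= 0) || any(cl <= 0) || any(v <= 0) || any(ka <= 0))
    stop("dose, cl, v, ka must be positive", call. = FALSE)
  ke <- cl / v
  out <- numeric(n)
  acc <- function(k, t, tau) exp(-k * t) / (1 - exp(-k * tau))
  deg <- abs(ka - ke) <= 1e-6 * pmax(ka, ke)
  if (any(!deg)) {
    i <- !deg
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (acc(ke[i], t[i], tau[i]) - acc(ka[i], t[i], tau[i]))
  }
  if (any(deg)) {
    i <- deg
    k <- (ka[i] + ke[i]) / 2
    E <- exp(-k * tau[i])
    out[i] <- dose[i] * ka[i] / v[i] * exp(-k * t[i]) *
      (t[i] * (1 - E) + tau[i] * E) / (1 - E)^2
  }
  out
}

#' Individual typical clearance under the covariate model
#'
#' Applies the multiplicative covariate model to each subject:
#' CL = cl_base * (1 + theta_18[g18]) * (1 + theta_6[g6]) *
#'      (1 + theta_sex * I(female)) * (1 + theta_wt * (WT - wt_center)) * ...
#' Covariates absent from `p$theta` contribute a multiplier of 1. Genotype
#' effects are named vectors over non-reference levels; levels not named
#' (including the reference) contribute 0.
#'
#' @param subjects subject table of a [pk_dataset()] (or a compatible
#'   data.frame).
#' @param p an [efv_params()] object.
#' @return Vector of clearances (L/h), one per subject row.
#' @export
individual_cl <- function(subjects, p) {
  n <- nrow(subjects)
  cl <- rep(p$cl_base, n)
  for (nm in names(p$theta)) {
    th <- p$theta[[nm]]
    mult <- if (nm == "sex") {
      1 + th * (subjects$sex == "female")
    } else if (nm == "weight") {
      1 + th * (subjects$weight - p$wt_center)
    } else if (nm == "age") {
      1 + th * (subjects$age - p$age_center)
    } else if (nm == "regimen") {
      1 + th * (subjects$regimen == "ART_plus_TB")
    } else if (nm == "cns") {
      1 + th * (subjects$cns == "yes")
    } else if (nm %in% names(genotype_levels)) {
      eff <- th[subjects[[nm]]]
      eff[is.na(eff)] <- 0
      1 + unname(eff)
    } else stop("unknown covariate in theta: ", nm, call. = FALSE)
    cl <- cl * mult
  }
  if (any(cl <= 0))
    stop("covariate model yields non-positive clearance for subject(s) ",
         paste(utils::head(subjects$id[cl <= 0], 5), collapse = ", "),
         call. = FALSE)
  cl
}

#' Predicted steady-state concentration for subjects
#'
#' Composes [individual_cl()] with [conc_ss()], applying the lognormal
#' between-subject deviation as `CL_i = CL * exp(eta)`.
#'
#' @param subjects subject table rows.
#' @param time time after dose (h), scalar or one per subject.
#' @param p an [efv_params()] object.
#' @param eta random-effect value(s), default 0 (population prediction).
#' @return Concentrations in ug/ml.
#' @export
predict_conc <- function(subjects, time, p, eta = 0) {
  cl <- individual_cl(subjects, p) * exp(eta)
  conc_ss(time, subjects$dose, subjects$tau, cl, p$v, p$ka)
}
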