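# Stepwise covariate selection on the change in objective function value
# (delta-OFV), with chi-square critical values at 5% (forward) and 1%
# (backward), a clinical-significance filter, and variance-explained
# bookkeeping.

#' Chi-square critical value for a delta-OFV test
#'
#' The `(1 - alpha)` quantile of the chi-square distribution with `df`
#' degrees of freedom: 3.84 for (0.05, 1), 6.63 for (0.01, 1), 5.99 for
#' (0.05, 2).
#'
#' @param alpha significance level in `(0, 1)`.
#' @param df degrees of freedom (>= 1).
#' @return Critical delta-OFV.
#' @export
chi2_threshold <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(df) || df < 1 || df != round(df))
    stop("df must be a positive integer", call. = FALSE)
  stats::qchisq(1 - alpha, df)
}

#' Percentage of between-subject variance explained
#'
#' `100 * (omega2_base - omega2_final) / omega2_base`: the share of the
#' base-model between-subject variance on clearance removed by the
#' covariates.
#'
#' @param omega2_base base-model variance (> 0).
#' @param omega2_final covariate-model variance.
#' @return Percentage (negative, with a warning, if the variance rose).
#' @export
variance_explained <- function(omega2_base, omega2_final) {
  if (!is.numeric(omega2_base) || omega2_base <= 0)
    stop("omega2_base must be positive", call. = FALSE)
  out <- 100 * (omega2_base - omega2_final) / omega2_base
  if (out < 0)
    warning("between-subject variance increased with covariates")
  out
}

empty_trace <- function() {
  data.frame(step = integer(), covariate = character(), df = integer(),
             delta_ofv = numeric(), p_value = numeric(),
             iiv_explained_pct = numeric(), decision = character(),
             stringsAsFactors = FALSE)
}

trace_row <- function(step, covariate, df, delta_ofv, omega2_parent,
                      omega2_child, decision) {
  data.frame(step = step, covariate = covariate, df = df,
             delta_ofv = delta_ofv,
             p_value = stats::pchisq(max(delta_ofv, 0), df,
                                     lower.tail = FALSE),
             iiv_explained_pct =
               100 * (omega2_parent - omega2_child) / omega2_parent,
             decision = decision, stringsAsFactors = FALSE)
}

fit_or_null <- function(ds, spec, init, control, label) {
  out <- tryCatch(fit_focei(ds, spec, init = init, control = control),
                  error = function(e) {
                    warning("fit failed for ", label, ": ",
                            conditionMessage(e))
                    NULL
                  })
  if (!is.null(out) && !out$converged) {
    warning("fit did not converge for ", label)
  }
  out
}

#' Forward inclusion of covariates by delta-OFV
#'
#' Starting from `base`, repeatedly fits each remaining candidate added
#' alone and includes the candidate with the largest delta-OFV exceeding
#' the chi-square critical value at `alpha` for its degrees of freedom
#' (strict inequality); stops when no candidate qualifies. Ties are
#' broken by larger delta-OFV, then lexicographic covariate name. A
#' candidate whose fit fails is skipped with a warning.
#'
#' @param ds a [pk_dataset()].
#' @param base base [model_spec()] (typically no covariates).
#' @param candidates covariate names to consider.
#' @param alpha forward significance level (default 0.05).
#' @param control a [focei_control()]; RSE computation is off by default
#'   here since only OFV differences are needed.
#' @param base_fit optional pre-computed fit of `base`.
#' @return List with elements `spec` (selected model), `trace`
#'   (selection trace data.frame), `fit` (fit of the selected model).
#' @export
forward_select <- function(ds, base = model_spec(),
                           candidates = candidate_covariates,
                           alpha = 0.05,
                           control = focei_control(compute_rse = FALSE),
                           base_fit = NULL) {
  spec <- base
  fit <- base_fit %||% fit_focei(ds, spec, control = control)
  trace <- empty_trace()
  remaining <- sort(setdiff(candidates, spec$covariates))
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(remaining) == 0) break
    trials <- list()
    for (cand in remaining) {
      cand_spec <- model_spec(c(spec$covariates, cand), v = spec$v,
                              ka = spec$ka, wt_center = spec$wt_center,
                              age_center = spec$age_center)
      df <- cov_df(cand_spec, ds$subjects) - cov_df(spec, ds$subjects)
      if (df == 0) next  # covariate constant in these data
      cand_fit <- fit_or_null(ds, cand_spec, fit$params, control, cand)
      if (is.null(cand_fit)) next
      trials[[cand]] <- list(spec = cand_spec, fit = cand_fit, df = df,
                             delta = fit$ofv - cand_fit$ofv)
    }
    if (length(trials) == 0) break
    deltas <- vapply(trials, `[[`, numeric(1), "delta")
    dfs <- vapply(trials, `[[`, numeric(1), "df")
    crit <- vapply(dfs, function(d) chi2_threshold(alpha, d), numeric(1))
    qualifies <- deltas > crit
    if (!any(qualifies)) {
      for (cand in names(trials))
        trace <- rbind(trace, trace_row(
          step, cand, trials[[cand]]$df, trials[[cand]]$delta,
          fit$params$omega2, trials[[cand]]$fit$params$omega2,
          "rejected"))
      break
    }
    pick <- names(trials)[qualifies][
      order(-deltas[qualifies], names(trials)[qualifies])][1]
    trace <- rbind(trace, trace_row(
      step, pick, trials[[pick]]$df, trials[[pick]]$delta,
      fit$params$omega2, trials[[pick]]$fit$params$omega2, "added"))
    spec <- trials[[pick]]$spec
    fit <- trials[[pick]]$fit
    remaining <- setdiff(remaining, pick)
  }
  list(spec = spec, trace = trace, fit = fit)
}

#' Backward elimination of covariates by delta-OFV
#'
#' Starting from `full`, repeatedly removes the covariate whose removal
#' increases the OFV the least, provided that increase does not exceed
#' the chi-square critical value at `alpha` for its degrees of freedom
#' (a covariate is retained only if its removal increases the OFV
#' strictly beyond the critical value); stops when every remaining
#' covariate is significant.
#'
#' @param ds a [pk_dataset()].
#' @param full starting [model_spec()].
#' @param alpha backward significance level (default 0.01).
#' @param control a [focei_control()].
#' @param full_fit optional pre-computed fit of `full`.
#' @return List with `spec`, `trace`, `fit` as in [forward_select()].
#' @export
backward_eliminate <- function(ds, full, alpha = 0.01,
                               control = focei_control(compute_rse = FALSE),
                               full_fit = NULL) {
  spec <- full
  fit <- full_fit %||% fit_focei(ds, spec, control = control)
  trace <- empty_trace()
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(spec$covariates) == 0) break
    trials <- list()
    for (cov in sort(spec$covariates)) {
      red_spec <- model_spec(setdiff(spec$covariates, cov), v = spec$v,
                             ka = spec$ka, wt_center = spec$wt_center,
                             age_center = spec$age_center)
      df <- cov_df(spec, ds$subjects) - cov_df(red_spec, ds$subjects)
      if (df == 0) next
      red_fit <- fit_or_null(ds, red_spec, fit$params, control, cov)
      if (is.null(red_fit)) next
      trials[[cov]] <- list(spec = red_spec, fit = red_fit, df = df,
                            increase = red_fit$ofv - fit$ofv)
    }
    if (length(trials) == 0) break
    inc <- vapply(trials, `[[`, numeric(1), "increase")
    dfs <- vapply(trials, `[[`, numeric(1), "df")
    crit <- vapply(dfs, function(d) chi2_threshold(alpha, d), numeric(1))
    removable <- inc <= crit
    if (!any(removable)) {
      for (cov in names(trials))
        trace <- rbind(trace, trace_row(
          step, cov, trials[[cov]]$df, trials[[cov]]$increase,
          trials[[cov]]$fit$params$omega2, fit$params$omega2,
          "retained"))
      break
    }
    pick <- names(trials)[removable][
      order(inc[removable], names(trials)[removable])][1]
    trace <- rbind(trace, trace_row(
      step, pick, trials[[pick]]$df, trials[[pick]]$increase,
      trials[[pick]]$fit$params$omega2, fit$params$omega2, "removed"))
    spec <- trials[[pick]]$spec
    fit <- trials[[pick]]$fit
  }
  list(spec = spec, trace = trace, fit = fit)
}

#' Stepwise covariate selection (forward then backward)
#'
#' Forward inclusion at the 5% level followed by backward elimination at
#' the 1% level, the conventional two-pass stepwise procedure for
#' delta-OFV covariate screening.
#'
#' @inheritParams forward_select
#' @param alpha_forward,alpha_backward significance levels for the two
#'   passes.
#' @return List with `spec`, `fit`, and the combined `trace` (forward
#'   steps then backward steps).
#' @export
select_covariates <- function(ds, base = model_spec(),
                              candidates = candidate_covariates,
                              alpha_forward = 0.05,
                              alpha_backward = 0.01,
                              control = focei_control(compute_rse = FALSE)) {
  fw <- forward_select(ds, base, candidates, alpha_forward, control)
  bw <- backward_eliminate(ds, fw$spec, alpha_backward, control,
                           full_fit = fw$fit)
  trace <- rbind(
    cbind(fw$trace, pass = rep("forward", nrow(fw$trace))),
    cbind(bw$trace, pass = rep("backward", nrow(bw$trace))))
  list(spec = bw$spec, fit = bw$fit, trace = trace)
}

#' Flag covariates below the clinical-significance threshold
#'
#' For each covariate retained in a fit, computes the maximal fractional
#' effect on clearance over its observed range (largest |theta| over the
#' genotype levels present, |theta| for binary covariates, and
#' |theta * (extreme - center)| for continuous ones) and flags those
#' below the threshold (default 20%).
#'
#' @param fit a `focei_fit`.
#' @param ds the fitted dataset (defines observed covariate ranges).
#' @param threshold fraction below which an effect is clinically
#'   irrelevant.
#' @return data.frame with columns `covariate`, `max_effect`, `flagged`.
#' @export
clinical_significance_filter <- function(fit, ds, threshold = 0.20) {
  p <- fit$params
  s <- ds$subjects
  out <- empty_clinical()
  for (nm in names(p$theta)) {
    th <- p$theta[[nm]]
    max_eff <- if (nm == "weight") {
      rng <- range(s$weight) - p$wt_center
      max(abs(th * rng))
    } else if (nm == "age") {
      rng <- range(s$age) - p$age_center
      max(abs(th * rng))
    } else if (nm %in% names(genotype_levels)) {
      present <- intersect(names(th), unique(s[[nm]]))
      if (length(present) == 0) 0 else max(abs(th[present]))
    } else max(abs(th))
    out <- rbind(out, data.frame(covariate = nm, max_effect = max_eff,
                                 flagged = max_eff < threshold,
                                 stringsAsFactors = FALSE))
  }
  out
}

empty_clinical <- function() {
  data.frame(covariate = character(), max_effect = numeric(),
             flagged = logical(), stringsAsFactors = FALSE)
}
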