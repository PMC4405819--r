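# Goodness-of-fit data products: population and individual predictions
# and individually weighted residuals per observation.

#' Goodness-of-fit table
#'
#' One record per observation: population prediction (`eta = 0`),
#' individual prediction (at the empirical-Bayes `eta_hat`), and the
#' individually weighted residual under the interaction convention,
#' `IWRES = (y - f_ind) / (sigma * f_ind)` with the residual standard
#' deviation evaluated at the individual prediction.
#'
#' @param ds the fitted [pk_dataset()].
#' @param fit a converged `focei_fit` with empirical-Bayes estimates.
#' @return data.frame with columns `id`, `time`, `conc`, `pred`,
#'   `ipred`, `iwres`.
#' @export
gof_table <- function(ds, fit) {
  o <- ds$observations
  idx <- match(o$id, ds$subjects$id)
  eta <- fit$ebes$eta[match(o$id, fit$ebes$id)]
  if (anyNA(eta))
    stop("missing empirical-Bayes estimate for subject(s): ",
         paste(unique(o$id[is.na(eta)]), collapse = ", "), call. = FALSE)
  s <- ds$subjects[idx, ]
  p <- fit$params
  pred <- predict_conc(s, o$time, p, eta = 0)
  ipred <- predict_conc(s, o$time, p, eta = eta)
  iwres <- (o$conc - ipred) / (sqrt(p$sigma2) * ipred)
  data.frame(id = o$id, time = o$time, conc = o$conc, pred = pred,
             ipred = ipred, iwres = iwres, stringsAsFactors = FALSE)
}
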