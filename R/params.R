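# Parameter container: fixed effects (typical clearance and multiplicative
# covariate effects), structural constants, and variance components.

#' Population PK parameter set
#'
#' The model estimates apparent oral clearance CL/F only; V/F and ka are
#' structural constants. Clearance for individual i is
#'
#'   CL_i = cl_base * prod(1 + theta_c * x_c) * exp(eta_i)
#'
#' with one multiplicative term per active covariate: indicator terms for
#' non-reference genotype levels and female sex, and linear terms per unit
#' of centred continuous covariates. `eta ~ N(0, omega2)` is the lognormal
#' between-subject deviation; the observation model is proportional,
#' `y = f * (1 + eps)`, `eps ~ N(0, sigma2)`.
#'
#' @param cl_base typical CL/F (L/h) at all-reference covariates
#'   (CYP2B6*18 TT, CYP2B6*6 GT, male, weight at `wt_center`).
#' @param theta named list of fractional effects. Genotype entries are
#'   named vectors over non-reference levels (`cyp2b6_18 = c(TC=, CC=)`,
#'   `cyp2b6_6 = c(GG=, TT=)`, ...); `sex` is the female effect; `weight`
#'   and `age` are per-unit slopes applied to the centred covariate.
#'   Absent entries contribute a multiplier of 1.
#' @param wt_center,age_center centering values (kg, years).
#' @param v,ka structural constants: V/F (L) and ka (1/h).
#' @param omega2 variance of eta (between-subject variability on CL).
#' @param sigma2 variance of the proportional residual error.
#' @return Object of class `efv_params`.
#' @export
efv_params <- function(cl_base, theta = list(), wt_center = 58,
                       age_center = 39, v = 150, ka = 0.18,
                       omega2 = 0, sigma2 = 0) {
  stopifnot(cl_base > 0, v > 0, ka > 0, omega2 >= 0, sigma2 >= 0)
  for (nm in names(theta)) {
    if (nm %in% c("weight", "age")) next
    if (any(1 + theta[[nm]] <= 0))
      stop("fractional effect for ", nm,
           " must keep 1 + theta positive", call. = FALSE)
  }
  structure(list(cl_base = cl_base, theta = theta, wt_center = wt_center,
                 age_center = age_center, v = v, ka = ka,
                 omega2 = omega2, sigma2 = sigma2),
            class = "efv_params")
}

#' Published final-model parameter estimates
#'
#' The final covariate model for 600 mg daily efavirenz: genotype-specific
#' typical clearances CL/F of 7.01 (CYP2B6*18 TT), 2.26 (TC) and 0.539
#' (CC) L/h, a +93.1% (CYP2B6*6 GG) and -63.4% (*6 TT) fractional effect
#' relative to *6 GT, +2.11%/kg body weight (centred at 58 kg), +22.2%
#' for females, V/F fixed at 150 L, ka at 0.18 1/h, between-subject
#' variance 0.494 (70.3 %CV) and proportional residual variance 0.12.
#' The *18 TC and CC effects are carried as fractional changes from the
#' TT clearance so the three genotype-specific clearances are recovered
#' exactly.
#'
#' @return An [efv_params()] object.
#' @export
efv_reference_params <- function() {
  efv_params(
    cl_base = 7.01,
    theta = list(
      cyp2b6_18 = c(TC = 2.26 / 7.01 - 1, CC = 0.539 / 7.01 - 1),
      cyp2b6_6  = c(GG = 0.931, TT = -0.634),
      weight    = 0.0211,
      sex       = 0.222
    ),
    wt_center = 58, v = 150, ka = 0.18,
    omega2 = 0.494, sigma2 = 0.12)
}

#' Genotype-specific typical clearances implied by a parameter set
#'
#' @param p an [efv_params()] object.
#' @return Named vector of CL/F (L/h) for CYP2B6*18 TT, TC, CC at
#'   otherwise-reference covariates.
#' @export
cl_by_cyp2b6_18 <- function(p) {
  f <- p$theta$cyp2b6_18 %||% c(TC = 0, CC = 0)
  c(TT = p$cl_base,
    TC = p$cl_base * (1 + unname(f["TC"])),
    CC = p$cl_base * (1 + unname(f["CC"])))
}

#' @export
print.efv_params <- function(x, ...) {
  cat("<efv_params>\n")
  cl18 <- cl_by_cyp2b6_18(x)
  cat(sprintf("  CL/F (L/h): TT %.3g  TC %.3g  CC %.3g   (*18 genotype)\n",
              cl18["TT"], cl18["TC"], cl18["CC"]))
  for (nm in setdiff(names(x$theta), "cyp2b6_18")) {
    v <- x$theta[[nm]]
    cat("  ", nm, ": ",
        paste(sprintf("%s%+.3g", if (is.null(names(v))) "" else
                      paste0(names(v), " "), v), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  V/F %g L, ka %g 1/h, wt_center %g kg\n",
              x$v, x$ka, x$wt_center))
  cat(sprintf("  omega2 %.4g (IIV %.1f %%CV), sigma2 %.4g\n",
              x$omega2, 100 * sqrt(x$omega2), x$sigma2))
  invisible(x)
}

# flat key-value serialization ------------------------------------------

param_file_keys <- c("CL18_TT", "CL18_TC", "CL18_CC", "FRAC6_GG",
                     "FRAC6_TT", "FRAC_FEMALE", "FRAC_WT_PER_KG",
                     "WT_CENTER", "V", "KA", "OMEGA2", "SIGMA2")

#' Write a parameter set to a flat key-value file
#'
#' @param p an [efv_params()] object (final-model shape).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  cl18 <- cl_by_cyp2b6_18(p)
  f6 <- p$theta$cyp2b6_6 %||% c(GG = 0, TT = 0)
  vals <- c(cl18["TT"], cl18["TC"], cl18["CC"], f6["GG"], f6["TT"],
            p$theta$sex %||% 0, p$theta$weight %||% 0,
            p$wt_center, p$v, p$ka, p$omega2, p$sigma2)
  writeLines(paste(param_file_keys, format(vals, digits = 17),
                   sep = " = "), path)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path flat key-value file.
#' @return An [efv_params()] object.
#' @export
read_params <- function(path) {
  ln <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- do.call(rbind, strsplit(ln, "\\s*=\\s*"))
  vals <- stats::setNames(as.numeric(kv[, 2]), trimws(kv[, 1]))
  missing <- setdiff(param_file_keys, names(vals))
  if (length(missing))
    stop("parameter file missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  efv_params(
    cl_base = unname(vals["CL18_TT"]),
    theta = list(
      cyp2b6_18 = c(TC = unname(vals["CL18_TC"] / vals["CL18_TT"] - 1),
                    CC = unname(vals["CL18_CC"] / vals["CL18_TT"] - 1)),
      cyp2b6_6 = c(GG = unname(vals["FRAC6_GG"]),
                   TT = unname(vals["FRAC6_TT"])),
      weight = unname(vals["FRAC_WT_PER_KG"]),
      sex = unname(vals["FRAC_FEMALE"])),
    wt_center = unname(vals["WT_CENTER"]), v = unname(vals["V"]),
    ka = unname(vals["KA"]), omega2 = unname(vals["OMEGA2"]),
    sigma2 = unname(vals["SIGMA2"]))
}
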