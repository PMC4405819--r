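# Synthetic cohort generator: reproduces the demographic and
# pharmacogenetic structure of the study population (n=185 HIV/TB cohort,
# 60 M / 125 F, sex-specific weight distributions, empirical genotype
# frequencies) and the steady-state sparse-sampling observation design.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort: 185 subjects, 125/185 female,
#' weights Normal(61.5, 10.1) kg for males and Normal(57.9, 11.3) kg for
#' females truncated to 35-120 kg, genotype frequencies equal to the
#' observed cohort proportions, 600 mg once daily, and a single plasma
#' sample drawn uniformly 12-15 h post dose at steady state.
#'
#' @param n_subjects number of subjects.
#' @param sex_fraction_female Bernoulli probability of female sex.
#' @param weight_mean_male,weight_sd_male,weight_mean_female,weight_sd_female
#'   sex-specific weight distribution (kg), truncated to `weight_range`.
#' @param age_mean_male,age_sd_male,age_mean_female,age_sd_female
#'   sex-specific age distribution (years).
#' @param genotype_freqs named list of per-locus genotype probabilities,
#'   each a vector over that locus's genotype levels summing to 1 (see
#'   [hwe_genotype_freqs()] for Hardy-Weinberg proportions from an allele
#'   frequency).
#' @param prop_tb proportion on concurrent rifampicin-based TB therapy.
#' @param prop_cns proportion with CNS adverse effects recorded.
#' @param dose daily dose (mg); `tau` dosing interval (h).
#' @param sampling_window `(t_lo, t_hi)` hours post dose for random
#'   sampling times.
#' @param n_samples_per_subject samples per subject when drawing times
#'   from the window.
#' @param times optional fixed sampling times (h); overrides the window
#'   (used for the richer replicate design in recovery experiments).
#' @param lloq lower limit of quantitation (ug/ml); simulated
#'   concentrations at or below it are redrawn.
#' @param weight_range truncation bounds for weight (kg).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 185,
                          sex_fraction_female = 125 / 185,
                          weight_mean_male = 61.52, weight_sd_male = 10.06,
                          weight_mean_female = 57.92,
                          weight_sd_female = 11.29,
                          age_mean_male = 40.2, age_sd_male = 9.14,
                          age_mean_female = 38.3, age_sd_female = 8.07,
                          genotype_freqs = table1_genotype_freqs(),
                          prop_tb = 90 / 185, prop_cns = 79 / 185,
                          dose = 600, tau = 24,
                          sampling_window = c(12, 15),
                          n_samples_per_subject = 1L,
                          times = NULL, lloq = 0,
                          weight_range = c(35, 120)) {
  stopifnot(n_subjects >= 0,
            sex_fraction_female >= 0, sex_fraction_female <= 1,
            prop_tb >= 0, prop_tb <= 1, prop_cns >= 0, prop_cns <= 1,
            dose > 0, tau > 0,
            sampling_window[1] < sampling_window[2],
            sampling_window[2] <= tau,
            n_samples_per_subject >= 1)
  for (g in names(genotype_levels)) {
    f <- genotype_freqs[[g]]
    if (is.null(f) || length(f) != 3 || any(f < 0) ||
        abs(sum(f) - 1) > 1e-8)
      stop("genotype_freqs$", g,
           " must be 3 non-negative frequencies summing to 1",
           call. = FALSE)
  }
  if (!is.null(times)) {
    stopifnot(all(times > 0), all(times <= tau))
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Observed cohort genotype frequencies
#'
#' Empirical genotype proportions of the study cohort, by locus, in the
#' level order of `genotype_levels` (counts: CYP2B6*6 GG/GT/TT =
#' 57/84/39, CYP2B6*18 TT/TC/CC = 132/47/6, CYP2A6*9 GG/GT/TT =
#' 110/0/24, CYP2A6*17 GG/GA/AA = 120/15/1, ABCB1 1236 CC/CT/TT =
#' 115/16/6).
#'
#' @return Named list of frequency triples.
#' @export
table1_genotype_freqs <- function() {
  list(cyp2b6_6   = c(57, 84, 39) / 180,
       cyp2b6_18  = c(132, 47, 6) / 185,
       cyp2a6_9   = c(110, 0, 24) / 134,
       cyp2a6_17  = c(120, 15, 1) / 136,
       abcb1_1236 = c(115, 16, 6) / 137)
}

#' Hardy-Weinberg genotype frequencies from a minor-allele frequency
#'
#' @param p minor-allele frequency in `[0, 1]`.
#' @return Frequency triple `((1-p)^2, 2p(1-p), p^2)` (homozygous
#'   reference, heterozygous, homozygous variant).
#' @export
hwe_genotype_freqs <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("allele frequency must be a single value in [0, 1]",
         call. = FALSE)
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

# Inverse-CDF truncated-normal sampler. Quantile coupling: with a shared
# uniform stream, samples are monotone in (mean, lo, hi), which the dose
# module exploits for common-random-number comparisons across strata.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort (subjects only)
#'
#' Draws subject covariates independently per locus/field from the
#' configured distributions. Deterministic given `seed`.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return A [pk_dataset()] with subjects and no observations.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = NULL) {
  with_seed(seed, {
    n <- cfg$n_subjects
    if (n == 0) {
      empty <- data.frame(
        id = character(0), sex = character(0), weight = numeric(0),
        age = numeric(0), cyp2b6_6 = character(0),
        cyp2b6_18 = character(0), cyp2a6_9 = character(0),
        cyp2a6_17 = character(0), abcb1_1236 = character(0),
        regimen = character(0), cns = character(0), dose = numeric(0),
        tau = numeric(0), stringsAsFactors = FALSE)
      return(pk_dataset(empty))
    }
    sex <- ifelse(stats::runif(n) < cfg$sex_fraction_female,
                  "female", "male")
    f <- sex == "female"
    weight <- numeric(n)
    weight[f] <- rtruncnorm_inv(sum(f), cfg$weight_mean_female,
                                cfg$weight_sd_female,
                                cfg$weight_range[1], cfg$weight_range[2])
    weight[!f] <- rtruncnorm_inv(sum(!f), cfg$weight_mean_male,
                                 cfg$weight_sd_male,
                                 cfg$weight_range[1], cfg$weight_range[2])
    age <- numeric(n)
    age[f] <- stats::rnorm(sum(f), cfg$age_mean_female, cfg$age_sd_female)
    age[!f] <- stats::rnorm(sum(!f), cfg$age_mean_male, cfg$age_sd_male)
    age <- pmax(age, 18)
    subjects <- data.frame(
      id = sprintf("S%03d", seq_len(n)), sex = sex, weight = weight,
      age = age, stringsAsFactors = FALSE)
    for (g in names(genotype_levels))
      subjects[[g]] <- sample(genotype_levels[[g]], n, replace = TRUE,
                              prob = cfg$genotype_freqs[[g]])
    subjects$regimen <- ifelse(stats::runif(n) < cfg$prop_tb,
                               "ART_plus_TB", "ART_only")
    subjects$cns <- ifelse(stats::runif(n) < cfg$prop_cns, "yes", "no")
    subjects$dose <- cfg$dose
    subjects$tau <- cfg$tau
    pk_dataset(subjects)
  })
}

#' Simulate steady-state concentration observations
#'
#' For each subject draws `eta ~ N(0, omega2)`, sampling times (fixed
#' `cfg$times`, or uniform in the sampling window), and proportional
#' errors `eps ~ N(0, sigma2)`; the observed concentration is
#' `y = f * (1 + eps)`. Draws giving `y <= lloq` are redrawn (resampling
#' rather than truncation keeps concentrations positive without biasing
#' the mean). Deterministic given `seed`.
#'
#' @param ds a [pk_dataset()] (observations, if any, are replaced).
#' @param p an [efv_params()] generating parameter set.
#' @param cfg a [cohort_config()] providing the observation design.
#' @param seed integer seed.
#' @return The dataset with simulated observations attached.
#' @export
simulate_observations <- function(ds, p, cfg = cohort_config(),
                                  seed = NULL) {
  s <- ds$subjects
  n <- nrow(s)
  if (n == 0) stop("no subjects to simulate", call. = FALSE)
  with_seed(seed, {
    eta <- stats::rnorm(n, 0, sqrt(p$omega2))
    if (!is.null(cfg$times)) {
      k <- length(cfg$times)
      time <- rep(cfg$times, times = n)
    } else {
      k <- cfg$n_samples_per_subject
      time <- stats::runif(n * k, cfg$sampling_window[1],
                           cfg$sampling_window[2])
    }
    idx <- rep(seq_len(n), each = k)
    cl <- individual_cl(s, p) * exp(eta)
    fpred <- conc_ss(time, s$dose[idx], s$tau[idx], cl[idx], p$v, p$ka)
    eps <- stats::rnorm(n * k, 0, sqrt(p$sigma2))
    y <- fpred * (1 + eps)
    for (tries in 1:100) {
      bad <- y <= cfg$lloq
      if (!any(bad)) break
      eps[bad] <- stats::rnorm(sum(bad), 0, sqrt(p$sigma2))
      y <- fpred * (1 + eps)
    }
    if (any(y <= cfg$lloq))
      stop("could not draw concentrations above the LLOQ", call. = FALSE)
    obs <- data.frame(id = s$id[idx], time = time, conc = y,
                      occ = 1L, stringsAsFactors = FALSE)
    pk_dataset(s, obs)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_cohort()] then
#' [simulate_observations()], with sub-seeds split from one root seed.
#'
#' @inheritParams simulate_observations
#' @param seed root seed.
#' @return A [pk_dataset()] with subjects and observations.
#' @export
simulate_dataset <- function(cfg = cohort_config(),
                             p = efv_reference_params(), seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    as.list(split_seed(seed, 2))
  ds <- generate_cohort(cfg, seed = seeds[[1]])
  simulate_observations(ds, p, cfg, seed = seeds[[2]])
}
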