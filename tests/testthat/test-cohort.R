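# Synthetic cohort generator: determinism, marginal structure, and the
# observation model.

test_that("generation is deterministic given a seed", {
  cfg <- cohort_config(n_subjects = 60)
  d1 <- simulate_dataset(cfg, efv_reference_params(), seed = 10)
  d2 <- simulate_dataset(cfg, efv_reference_params(), seed = 10)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(cfg, efv_reference_params(), seed = 11)
  expect_false(identical(d1$observations$conc, d3$observations$conc))
})

test_that("n = 0 yields an empty cohort", {
  ds <- generate_cohort(cohort_config(n_subjects = 0), seed = 1)
  expect_equal(nrow(ds$subjects), 0)
})

test_that("Hardy-Weinberg genotype frequencies", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0), c(1, 0, 0))
  # minor-allele frequency implied by the cohort's CYP2B6*6 counts
  p_t <- (84 + 2 * 39) / 360
  expect_equal(p_t, 0.45)
  expect_equal(hwe_genotype_freqs(p_t), c(0.3025, 0.495, 0.2025))
  # close to the observed 57/84/39 genotype proportions
  expect_lt(max(abs(hwe_genotype_freqs(p_t) - c(57, 84, 39) / 180)),
            0.03)
  expect_error(hwe_genotype_freqs(1.3), "\\[0, 1\\]")
})

test_that("marginal structure matches the configured cohort", {
  cfg <- cohort_config(n_subjects = 3000)
  ds <- generate_cohort(cfg, seed = 5)
  s <- ds$subjects
  expect_equal(mean(s$sex == "female"), 125 / 185, tolerance = 0.05)
  f <- s$sex == "female"
  expect_equal(mean(s$weight[f]), 57.92, tolerance = 0.02)
  expect_equal(mean(s$weight[!f]), 61.52, tolerance = 0.02)
  expect_equal(sd(s$weight[f]), 11.29, tolerance = 0.06)
  prop18 <- unname(prop.table(table(
    factor(s$cyp2b6_18, c("TT", "TC", "CC")))))
  expect_lt(max(abs(as.numeric(prop18) - c(132, 47, 6) / 185)), 0.025)
  expect_true(all(s$weight >= 35 & s$weight <= 120))
})

test_that("zero-variance simulation reproduces the population curve and
           dose scaling is exact under matched seeds", {
  p0 <- efv_params(cl_base = 7.01,
                   theta = efv_reference_params()$theta,
                   omega2 = 0, sigma2 = 0)
  cfg <- cohort_config(n_subjects = 20)
  ds <- simulate_dataset(cfg, p0, seed = 8)
  idx <- match(ds$observations$id, ds$subjects$id)
  expect_equal(ds$observations$conc,
               predict_conc(ds$subjects[idx, ], ds$observations$time,
                            p0),
               tolerance = 1e-12)

  p <- efv_reference_params()
  cohort <- generate_cohort(cfg, seed = 8)
  lo <- simulate_observations(cohort, p, cfg, seed = 3)
  cohort2 <- cohort
  cohort2$subjects$dose <- cohort$subjects$dose * 2
  hi <- simulate_observations(cohort2, p, cfg, seed = 3)
  expect_equal(hi$observations$conc, 2 * lo$observations$conc,
               tolerance = 1e-12)
})

test_that("log-concentration spread matches the quadrature-based
           theoretical value", {
  # single fixed sampling time and a reference-genotype population so
  # the observations are iid; theory by numerical integration over the
  # eta and eps densities (eps renormalized on 1+eps > 0 as in the
  # resampling scheme)
  p <- efv_reference_params()
  p$theta <- list(); p$cl_base <- 7.01
  cfg <- cohort_config(n_subjects = 10000, times = 13.5,
                       sex_fraction_female = 0)
  cfg$weight_sd_male <- 1e-6   # hold weight at its mean
  ds <- simulate_dataset(cfg, p, seed = 77)
  logf <- function(e) log(conc_ss(13.5, 600, 24, 7.01 * exp(e)))
  dn_eta <- function(e) dnorm(e, 0, sqrt(p$omega2))
  m1 <- integrate(function(e) sapply(e, logf) * dn_eta(e), -6, 6,
                  rel.tol = 1e-10)$value
  m2 <- integrate(function(e) sapply(e, logf)^2 * dn_eta(e), -6, 6,
                  rel.tol = 1e-10)$value
  sde <- sqrt(p$sigma2)
  z <- pnorm(-1 / sde, lower.tail = FALSE)
  e1 <- integrate(function(x) log1p(x) * dnorm(x, 0, sde) / z,
                  -1 + 1e-12, 6 * sde)$value
  e2 <- integrate(function(x) log1p(x)^2 * dnorm(x, 0, sde) / z,
                  -1 + 1e-12, 6 * sde)$value
  sd_theory <- sqrt((m2 - m1^2) + (e2 - e1^2))
  expect_equal(sd(log(ds$observations$conc)), sd_theory,
               tolerance = 0.03)
})
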