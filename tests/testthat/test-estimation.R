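# Empirical-Bayes modes, the FOCE-I objective, and the outer fit.

test_that("EBE mode matches a dense grid search on a 1-obs instance", {
  p <- efv_params(cl_base = 7, omega2 = 0.4, sigma2 = 0.1)
  s <- ref_subject()
  obs <- data.frame(id = "R01", time = 13.5, conc = 5.5, occ = 1L)
  ds <- pk_dataset(s, obs)
  hat <- ebe(ds, p)
  grid <- seq(-5, 5, by = 1e-4)
  g <- vapply(grid, function(e) {
    f <- predict_conc(s, 13.5, p, eta = e)
    (5.5 - f)^2 / (p$sigma2 * f^2) + log(p$sigma2 * f^2) +
      e^2 / p$omega2
  }, numeric(1))
  expect_equal(hat$eta, grid[which.min(g)], tolerance = 1e-4)
  expect_gt(hat$curvature, 0)
})

test_that("shrinkage limits behave: omega2 -> 0 gives eta -> 0, and an
           exact population match gives eta = 0", {
  p_small <- efv_params(cl_base = 7, omega2 = 1e-8, sigma2 = 0.1)
  s <- ref_subject()
  ds <- pk_dataset(s, data.frame(id = "R01", time = 13.5, conc = 5.5,
                                 occ = 1L))
  expect_lt(abs(ebe(ds, p_small)$eta), 1e-3)

  # with the interaction convention the log-variance term shifts the
  # mode off zero by O(sigma2) even when the observation equals the
  # population prediction; the mode vanishes as sigma2 -> 0
  for (s2 in c(1e-2, 1e-3)) {
    p <- efv_params(cl_base = 7, omega2 = 0.4, sigma2 = s2)
    y_pop <- predict_conc(s, 13.5, p, eta = 0)
    ds2 <- pk_dataset(s, data.frame(id = "R01", time = 13.5,
                                    conc = y_pop, occ = 1L))
    expect_lt(abs(ebe(ds2, p)$eta), 2 * s2)
  }
})

test_that("FOCE-I objective is within 1% of 64-node adaptive
           Gauss-Hermite quadrature on toy instances", {
  base <- efv_params(cl_base = 7, omega2 = 0.4, sigma2 = 0.1)
  cfg <- cohort_config(n_subjects = 5, times = c(2, 13.5, 24))
  ds <- simulate_dataset(cfg, base, seed = 17)
  jitter <- list(c(1, 1, 1), c(1.3, 0.7, 1.4), c(0.8, 1.5, 0.6))
  for (j in jitter) {
    p <- efv_params(cl_base = 7 * j[1], omega2 = 0.4 * j[2],
                    sigma2 = 0.1 * j[3])
    o <- ofv_focei(ds, p, model_spec())
    full <- ofv_full_constants(o, nrow(ds$observations),
                               nrow(ds$subjects))
    expect_equal(full, agq_m2ll(ds, p), tolerance = 0.01)
  }
})

test_that("the objective is additive over independent subjects", {
  p <- efv_params(cl_base = 7, omega2 = 0.4, sigma2 = 0.1)
  cfg <- cohort_config(n_subjects = 4, times = c(2, 13.5))
  ds <- simulate_dataset(cfg, p, seed = 9)
  o1 <- ofv_focei(ds, p, model_spec())
  s2 <- rbind(ds$subjects,
              transform(ds$subjects, id = paste0(id, "b")))
  o2obs <- rbind(ds$observations,
                 transform(ds$observations, id = paste0(id, "b")))
  ds2 <- pk_dataset(s2, o2obs)
  expect_equal(ofv_focei(ds2, p, model_spec()), 2 * o1,
               tolerance = 1e-8)
})

test_that("delta-OFV is invariant to the additive-constant convention", {
  p0 <- efv_params(cl_base = 7, omega2 = 0.4, sigma2 = 0.1)
  p1 <- efv_params(cl_base = 8, omega2 = 0.4, sigma2 = 0.1)
  cfg <- cohort_config(n_subjects = 6, times = c(13.5))
  ds <- simulate_dataset(cfg, p0, seed = 33)
  d_dropped <- ofv_focei(ds, p1) - ofv_focei(ds, p0)
  n <- nrow(ds$observations); m <- nrow(ds$subjects)
  d_full <- ofv_full_constants(ofv_focei(ds, p1), n, m) -
    ofv_full_constants(ofv_focei(ds, p0), n, m)
  expect_equal(d_dropped, d_full, tolerance = 1e-10)
})

test_that("perturbing parameters away from truth increases the
           objective on a large cohort", {
  p <- efv_reference_params()
  cfg <- recovery_cfg(300)
  ds <- simulate_dataset(cfg, p, seed = 4)
  spec <- final_spec()
  o_true <- ofv_focei(ds, p, spec)
  for (fac in c(0.7, 1.4)) {
    p_bad <- p; p_bad$cl_base <- p$cl_base * fac
    expect_gt(ofv_focei(ds, p_bad, spec), o_true)
  }
})

test_that("noise-free data with negligible variability recover the
           generating clearance to optimizer tolerance", {
  p <- efv_params(cl_base = 7.01, omega2 = 1e-4, sigma2 = 1e-4)
  cfg <- cohort_config(n_subjects = 40, times = c(2, 13.5, 24))
  ds <- simulate_dataset(cfg, p, seed = 2)
  fit <- fit_focei(ds, model_spec(),
                   control = focei_control(compute_rse = FALSE))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["cl_base"]], 7.01, tolerance = 0.005)
})

test_that("RSE scales roughly as 1/sqrt(n) and flags flat directions
           instead of crashing", {
  p <- efv_reference_params()
  spec <- final_spec()
  fits <- lapply(c(100, 400), function(n) {
    ds <- simulate_dataset(recovery_cfg(n), p, seed = 8)
    fit_focei(ds, spec)
  })
  r_small <- fits[[1]]$rse[["cl_base"]]
  r_big <- fits[[2]]$rse[["cl_base"]]
  expect_false(is.na(r_small) || is.na(r_big))
  # quadrupling the cohort should halve the RSE, within Monte-Carlo slack
  expect_gt(r_small / r_big, 1.3)
  expect_lt(r_small / r_big, 3.1)
  # same order as the reported 10% precision on the base clearance
  expect_gt(r_big, 1); expect_lt(r_big, 30)
})
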