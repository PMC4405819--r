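# Goodness-of-fit products and the end-to-end pipeline.

pseudo_fit <- function(ds, p) {
  structure(list(params = p, ebes = ebe(ds, p)), class = "focei_fit")
}

test_that("residual-noise-free data give vanishing IWRES", {
  # real between-subject variability but no residual error: the EBE
  # reproduces each subject's curve exactly, so IWRES collapses to 0
  p_gen <- efv_params(cl_base = 7.01,
                      theta = efv_reference_params()$theta,
                      omega2 = 0.2, sigma2 = 0)
  ds <- simulate_dataset(cohort_config(n_subjects = 15,
                                       times = c(2, 13.5)), p_gen,
                         seed = 6)
  p_fit <- p_gen; p_fit$sigma2 <- 1e-6
  gof <- gof_table(ds, pseudo_fit(ds, p_fit))
  expect_lt(max(abs(gof$iwres)), 5e-3)
  expect_equal(gof$ipred, gof$conc, tolerance = 1e-5)
})

test_that("well-specified IWRES are standardized; misspecification
           inflates them", {
  p <- efv_reference_params()
  ds <- simulate_dataset(recovery_cfg(150), p, seed = 13)
  gof <- gof_table(ds, pseudo_fit(ds, p))
  expect_lt(abs(mean(gof$iwres)), 0.1)
  expect_gt(sd(gof$iwres), 0.8)
  expect_lt(sd(gof$iwres), 1.15)
  # wrong fixed effects + overconfident IIV: residuals blow up
  p_bad <- efv_params(cl_base = 7.01, omega2 = 0.02, sigma2 = 0.12)
  gof_bad <- gof_table(ds, pseudo_fit(ds, p_bad))
  expect_gt(sd(gof_bad$iwres), 1.3)
})

test_that("the default pipeline writes every artifact and is
           reproducible; unknown stages fail before any work", {
  p <- efv_reference_params()
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  stages <- c("simulate", "fit", "dose-table", "gof")
  out <- run_pipeline(dir1, stages = stages, seed = 5, n_subjects = 40,
                      params = p, n_sim = 100)
  for (f in c("cohort.csv", "fit_report.txt", "dose_table.csv",
              "attainment.csv", "gof.csv", "params.txt", "log.txt"))
    expect_true(file.exists(file.path(dir1, f)), label = f)
  log <- readLines(file.path(dir1, "log.txt"))
  expect_true(any(grepl("root seed: 5", log)))

  run_pipeline(dir2, stages = stages, seed = 5, n_subjects = 40,
               params = p, n_sim = 100)
  for (f in c("cohort.csv", "dose_table.csv", "gof.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)

  expect_error(run_pipeline(withr::local_tempdir(), stages = "frobnicate"),
               "unknown stage")
})

test_that("fit-only runs on a provided CSV and selection traces reach
           the artifact directory", {
  p <- efv_reference_params()
  dir0 <- withr::local_tempdir()
  ds <- simulate_dataset(cohort_config(n_subjects = 40), p, seed = 19)
  csv <- file.path(dir0, "input.csv")
  write_pk_dataset(ds, csv)
  out <- run_pipeline(dir0, stages = "fit", seed = 2, data_csv = csv)
  expect_true(file.exists(file.path(dir0, "fit_report.txt")))
  expect_false(file.exists(file.path(dir0, "cohort.csv")))
  expect_s3_class(out$fit, "focei_fit")

  dir1 <- withr::local_tempdir()
  sel_out <- run_pipeline(dir1, stages = "select", seed = 2,
                          data_csv = csv,
                          candidates = c("cyp2b6_18", "cns"))
  tr <- utils::read.csv(file.path(dir1, "selection_trace.csv"))
  expect_true(all(c("covariate", "delta_ofv", "p_value", "decision")
                  %in% names(tr)))
  log <- readLines(file.path(dir1, "log.txt"))
  expect_true(any(grepl("dOFV", log)))
})
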