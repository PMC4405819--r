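# Dataset construction, validation and the NONMEM-style CSV round trip.

toy_csv <- function(path, extra_row = NULL) {
  lines <- c(
    "ID,TIME,DV,DOSE,WT,SEX,CYP2B6_6,CYP2B6_18,CYP2A6_9,CYP2A6_17,ABCB1,GRP,CNS",
    "P1,13.5,2.4,600,62,0,GT,TT,GG,GG,CC,ART_only,no",
    "P2,12.8,5.1,600,55,1,TT,TC,GG,GG,CC,ART_plus_TB,yes",
    extra_row)
  writeLines(lines, path)
  path
}

test_that("a toy CSV parses into subjects and observations", {
  path <- toy_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_pk_dataset(path)
  expect_s3_class(ds, "pk_dataset")
  expect_equal(nrow(ds$subjects), 2)
  expect_equal(nrow(ds$observations), 2)
  expect_equal(ds$subjects$sex, c("male", "female"))
  expect_equal(ds$subjects$tau, c(24, 24))      # default interval
  expect_equal(ds$observations$conc, c(2.4, 5.1))
})

test_that("invalid genotype strings are rejected with the row number", {
  path <- toy_csv(withr::local_tempfile(fileext = ".csv"),
                  "P3,13.0,1.0,600,70,0,GA,TT,GG,GG,CC,ART_only,no")
  expect_error(read_pk_dataset(path), "CYP2B6_6.*GA.*row 3")
})

test_that("missing required columns are named in the error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,DOSE,WT,SEX,CYP2B6_6,CYP2B6_18,CYP2A6_9,CYP2A6_17,ABCB1",
               "P1,13.5,600,62,0,GT,TT,GG,GG,CC"), path)
  expect_error(read_pk_dataset(path), "DV")
})

test_that("rows with missing DV are dropped with a message", {
  path <- toy_csv(withr::local_tempfile(fileext = ".csv"),
                  "P3,13.0,.,600,70,0,GT,TT,GG,GG,CC,ART_only,no")
  expect_message(ds <- read_pk_dataset(path), "dropped")
  expect_equal(nrow(ds$observations), 2)
})

test_that("write then read is the identity on a synthetic cohort", {
  cfg <- cohort_config(n_subjects = 25, n_samples_per_subject = 2)
  ds <- simulate_dataset(cfg, efv_reference_params(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  # row count property: one line per observation plus the header
  expect_length(readLines(path), nrow(ds$observations) + 1)
  ds2 <- read_pk_dataset(path)
  expect_equal(ds2$subjects[order(ds2$subjects$id), ],
               ds$subjects[order(ds$subjects$id), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ds2$observations$conc, ds$observations$conc,
               tolerance = 1e-12)
  expect_equal(ds2$observations$time, ds$observations$time,
               tolerance = 1e-12)
  expect_equal(ds2$observations$occ, ds$observations$occ)
  expect_equal(length(unique(ds2$subjects$id)), 25)
})

test_that("datasets with no observations cannot be written", {
  ds <- generate_cohort(cohort_config(n_subjects = 3), seed = 1)
  expect_error(write_pk_dataset(ds, withr::local_tempfile()),
               "no observations")
})

test_that("validation catches structural violations", {
  s <- ref_subject(2)
  expect_error(pk_dataset(transform(s, weight = c(60, -4))), "weight")
  expect_error(pk_dataset(transform(s, cyp2b6_18 = "GA")), "cyp2b6_18")
  expect_error(pk_dataset(s, data.frame(id = "nope", time = 13, conc = 1,
                                        occ = 1L)),
               "unknown subject")
  expect_error(pk_dataset(s, data.frame(id = "R01", time = 30, conc = 1,
                                        occ = 1L)),
               "tau")
})

test_that("parameter files round-trip", {
  p <- efv_reference_params()
  path <- withr::local_tempfile(fileext = ".txt")
  write_params(p, path)
  p2 <- read_params(path)
  expect_equal(p2$cl_base, p$cl_base, tolerance = 1e-12)
  expect_equal(p2$theta$cyp2b6_18, p$theta$cyp2b6_18, tolerance = 1e-12)
  expect_equal(p2$omega2, p$omega2, tolerance = 1e-12)
  writeLines(grep("OMEGA2", readLines(path), invert = TRUE,
                  value = TRUE), path)
  expect_error(read_params(path), "OMEGA2")
})
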