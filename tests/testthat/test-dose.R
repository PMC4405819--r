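# Monte-Carlo window attainment and dose recommendation.

test_that("attainment proportions are proportions and sum to one", {
  p <- efv_reference_params()
  st <- stratum("TT", "GT", "female", "<58")
  for (dose in c(200, 600)) {
    w <- window_attainment(st, dose, p, n = 500, seed = 3)
    expect_equal(w$p_below + w$p_within + w$p_above, 1,
                 tolerance = 1e-12)
    expect_true(all(unlist(w[c("p_below", "p_within", "p_above")]) >= 0))
  }
})

test_that("under common random numbers p_above is non-decreasing and
           p_below non-increasing in dose", {
  p <- efv_reference_params()
  rec <- recommend_dose(stratum("TT", "GG", "male", ">58"), p,
                        n = 800, seed = 5)
  expect_true(all(diff(rec$window$p_above) >= 0))
  expect_true(all(diff(rec$window$p_below) <= 0))
})

test_that("with zero variability all mass falls in the bin the
           deterministic concentration range dictates", {
  p0 <- efv_reference_params()
  p0$omega2 <- 0; p0$sigma2 <- 0
  st <- stratum("TT", "TT", "female", "<58")
  # deterministic concentration range over weight x time extremes
  cl_rng <- range(individual_cl(
    ref_subject(4, weight = c(35, 35, 58, 58), sex = "female",
                g18 = "TT", g6 = "TT"), p0))
  for (dose in c(150, 1200)) {
    conc_rng <- range(conc_ss(c(12, 15, 12, 15), dose, 24,
                              rep(cl_rng, each = 2)))
    w <- window_attainment(st, dose, p0, n = 400, seed = 9)
    if (conc_rng[1] > 4) expect_equal(w$p_above, 1)
    else if (conc_rng[2] < 1) expect_equal(w$p_below, 1)
    else if (conc_rng[1] >= 1 && conc_rng[2] <= 4)
      expect_equal(w$p_within, 1)
  }
})

test_that("a single-dose candidate set is a forced choice and every
           *6 TT stratum is recommended the floor dose", {
  p <- efv_reference_params()
  rec <- recommend_dose(stratum("TT", "GG", "male", ">58"), p,
                        doses = 600, n = 200, seed = 1)
  expect_equal(rec$recommended_dose, 600)

  tab <- build_dose_table(p, n = 400, seed = 7)
  expect_equal(nrow(tab), 36)
  expect_true(all(tab$recommended_dose[tab$cyp2b6_6 == "TT"] == 200))
  tab2 <- build_dose_table(p, n = 400, seed = 7)
  expect_identical(tab, tab2)   # deterministic given seed
})

test_that("faster-clearing strata never get a lower dose than strata
           they dominate, under common random numbers", {
  p <- efv_reference_params()
  rec1 <- function(st) recommend_dose(st, p, n = 600,
                                      seed = 11)$recommended_dose
  # pairs ordered componentwise in clearance (genotype activity, sex,
  # weight class), simulated on the same uniform stream
  pairs <- list(
    list(stratum("TT", "GG", "female", ">58"),
         stratum("TT", "GT", "female", ">58")),
    list(stratum("TT", "GT", "male", ">58"),
         stratum("TC", "GT", "male", ">58")),
    list(stratum("TT", "GT", "female", ">58"),
         stratum("TT", "GT", "female", "<58")),
    list(stratum("TT", "GG", "female", ">58"),
         stratum("TT", "GG", "male", ">58")),
    list(stratum("TC", "GG", "female", ">58"),
         stratum("CC", "TT", "male", "<58")))
  for (pr in pairs) expect_gte(rec1(pr[[1]]), rec1(pr[[2]]))
})

test_that("dose-table comparison flags agreement per stratum", {
  p <- efv_reference_params()
  tab <- build_dose_table(p, n = 300, seed = 2)
  cmp <- compare_dose_tables(tab)
  expect_equal(nrow(cmp), 36)
  # the robust floor-dose strata agree with the reference grid
  expect_true(all(cmp$agrees[cmp$cyp2b6_6 == "TT"]))
})
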