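test_that("orthant calibration inverts the arcsine relation and is confirmed by Monte Carlo", {
  expect_equal(calibrate_within_correlation(0.25), 0)
  rho <- calibrate_within_correlation(0.32)
  expect_equal(rho, sin(2 * pi * 0.07), tolerance = 1e-12)
  expect_equal(0.25 + asin(rho) / (2 * pi), 0.32, tolerance = 1e-12)
  # comonotone limit
  expect_gt(calibrate_within_correlation(0.4999), 0.999)
  expect_error(calibrate_within_correlation(0.2), "0.25")
  expect_error(calibrate_within_correlation(0.5), "0.25")
  # independent bivariate-normal Monte-Carlo cross-check of the orthant mass
  set.seed(101)
  n <- 2e5
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  p_hat <- mean(z1 >= 0 & z2 >= 0)
  expect_lt(abs(p_hat - 0.32), 3 * sqrt(0.32 * 0.68 / n))
})

test_that("marginal medians of generated measures converge to exp(log_mean)", {
  cfg <- cohort_config(n_subjects = 2e4, seed = 202)
  co <- simulate_cohort(cfg)
  # sign test: P(value >= true median) = 1/2; binomial 3-SE band
  for (sx in c("M", "F")) {
    target <- if (sx == "F") 0.609 else 0.663
    v <- co$r_imt_mm[co$sex == sx]
    p_hat <- mean(v >= target)
    expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / length(v)))
  }
  expect_lt(abs(stats::median(co$r_imt_mm[co$sex == "F"]) - 0.609), 0.01)
})

test_that("per-side geometry prevalence follows the orthant formula", {
  # independence: 25/25/25/25
  cfg0 <- cohort_config(n_subjects = 12000, rho_within = 0, rho_between = 0,
                        seed = 7)
  cl0 <- classify_cohort(simulate_cohort(cfg0),
                         medians = reference_medians())
  pr0 <- prop.table(table(cl0$r_geometry))
  se <- 3 * sqrt(0.25 * 0.75 / nrow(cl0))
  for (lvl in geometry_levels())
    expect_lt(abs(pr0[[lvl]] - 0.25), se)
  # calibrated: 32/18/18/32 against the generator's true medians
  cfg <- cohort_config(n_subjects = 12000, seed = 8)
  cl <- classify_cohort(simulate_cohort(cfg), medians = reference_medians())
  pr <- prop.table(table(cl$r_geometry))
  expect_lt(abs(pr[["BOTH"]] - 0.32), 3 * sqrt(0.32 * 0.68 / nrow(cl)))
  expect_lt(abs(pr[["NEITHER"]] - 0.32), 3 * sqrt(0.32 * 0.68 / nrow(cl)))
  expect_lt(abs(pr[["IMT_ONLY"]] - 0.18), 3 * sqrt(0.18 * 0.82 / nrow(cl)))
})

test_that("phenotype-1 prevalence is non-decreasing in the right-left correlation", {
  prev <- sapply(c(0, 0.35, 0.7), function(rb) {
    cfg <- cohort_config(n_subjects = 8000, rho_between = rb, seed = 33)
    cl <- classify_cohort(simulate_cohort(cfg), medians = reference_medians())
    mean(cl$phenotype_id == 1)
  })
  expect_true(all(diff(prev) > 0))
})

test_that("outcome generation matches the exponential-censoring closed form", {
  # all hazards equal: 11-yr mean follow-up at 0.0016/yr gives ~1.7% incidence
  lam <- 0.0016
  flat <- stats::setNames(rep(0, 10), as.character(1:10))
  cfg <- cohort_config(n_subjects = 3e4, baseline_hazard = lam,
                       log_hazard_by_phenotype = flat, seed = 99)
  co <- simulate_cohort(cfg)
  # exact incidence under Uniform(10,12) censoring:
  p_exact <- 1 - (exp(-10 * lam) - exp(-12 * lam)) / (2 * lam)
  expect_equal(round(100 * p_exact, 1), 1.7)  # the closed-form oracle value
  p_hat <- mean(co$event)
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / nrow(co)))
  expect_true(all(co$time_years > 0))
  expect_true(all(co$time_years[co$event == 1] <= 12))
})

test_that("zero baseline hazard yields zero events and censoring stays in window", {
  cfg <- cohort_config(n_subjects = 500, baseline_hazard = 0, seed = 4)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$event), 0L)
  expect_true(all(co$time_years >= 10 & co$time_years <= 12))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(n_subjects = 300, seed = 123)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- cohort_config(n_subjects = 300, seed = 124)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("configuration errors name the offending parameters", {
  expect_error(cohort_config(rho_within = 1.2), "rho_within")
  expect_error(cohort_config(censor_min_years = 13), "censor_min")
  expect_error(cohort_config(baseline_hazard = -1), "baseline_hazard")
  bad_map <- stats::setNames(rep(0, 9), as.character(1:9))
  expect_error(cohort_config(log_hazard_by_phenotype = bad_map), "10")
})

test_that("cohort CSV round-trips through the fixed schema and rejects violations", {
  co <- small_cohort(n = 50, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
    "subject_id,sex,age,race,height_cm,r_imt_mm,l_imt_mm,r_dia_mm,l_dia_mm,event,time_years,prevalent_stroke")
  back <- read_cohort_csv(path)
  expect_equal(back$r_imt_mm, co$r_imt_mm, tolerance = 1e-12)
  bad <- co; bad$event[3] <- 2L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(bad, path2)
  expect_error(read_cohort_csv(path2), "event.*row|row")
})
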