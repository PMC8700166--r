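test_that("generation is bitwise deterministic given the seed", {
  a <- generate_cohort(cohort_config(n = 200, seed = 71))
  b <- generate_cohort(cohort_config(n = 200, seed = 71))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n = 200, seed = 72))
  expect_false(identical(a, c))
})

test_that("marginals match the configured population", {
  cohort <- generate_cohort(cohort_config(n = 5000, seed = 73))
  expect_equal(mean(cohort$mgfr_ml_min_173), 67, tolerance = 2 / 67)
  expect_equal(sd(cohort$mgfr_ml_min_173), 28, tolerance = 2 / 28)
  expect_true(all(cohort$mgfr_ml_min_173 >= 3 &
                    cohort$mgfr_ml_min_173 <= 183))
  expect_equal(mean(cohort$age_years), 56, tolerance = 2 / 56)
  expect_true(all(cohort$age_years >= 18 & cohort$age_years <= 88))
  expect_equal(mean(cohort$sex == "M"), 0.55, tolerance = 0.05)
  bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  expect_equal(mean(bmi), 30, tolerance = 0.1)
})

test_that("marker links have the physiological directionality and positivity", {
  cohort <- generate_cohort(cohort_config(n = 5000, seed = 74))
  for (col in c("scr_umol_l", "scys_mg_l", "valine_umol_l",
                "myo_inositol_umol_l")) {
    expect_true(all(cohort[[col]] > 0))
  }
  rho <- function(col) cor(cohort[[col]], cohort$mgfr_ml_min_173,
                           method = "spearman")
  expect_lt(rho("myo_inositol_umol_l"), 0)
  expect_lt(rho("scr_umol_l"), 0)
  expect_lt(rho("scys_mg_l"), 0)
  expect_gt(rho("valine_umol_l"), 0)
})

test_that("invalid generator configs fail before sampling", {
  expect_error(cohort_config(n = 0), "n must")
  expect_error(cohort_config(mgfr_sd = -1), "positive")
  expect_error(cohort_config(mgfr_range = c(10, 5)), "increasing")
  expect_error(cohort_config(male_fraction = 1.5), "male_fraction")
  bad_links <- default_marker_links()
  bad_links$valine$mgfr_log_slope <- -0.2
  expect_error(cohort_config(marker_links = bad_links), "valine")
  bad_links2 <- default_marker_links()
  bad_links2$creatinine$mgfr_log_slope <- 0.5
  expect_error(cohort_config(marker_links = bad_links2), "creatinine")
})

test_that("richer marker set lowers CV error when the signal is present", {
  cohort <- simulate_mgfr(generate_cohort(cohort_config(n = 1000, seed = 75)),
                          seed = 76)
  multi <- model_formula(c("log(cystatin_c)", "log(creatinine)",
                           "log(valine)", "myo_inositol"), response = "log")
  single <- model_formula(c("log(creatinine)", "age"), response = "log")
  cv_multi <- cross_validate(multi, cohort, seed = 5)
  cv_single <- cross_validate(single, cohort, seed = 5)
  expect_lt(cv_multi$cv_mae_mean, cv_single$cv_mae_mean)
})

test_that("stratified partition preserves cell proportions to one sample", {
  cohort <- generate_cohort(cohort_config(n = 100, seed = 77))
  parts <- stratified_partition(cohort, c(0.44, 0.24, 0.32), strata = "sex",
                                seed = 9)
  expect_equal(vapply(parts, nrow, 0L),
               c(development = 44L, internal = 24L, external = 32L))
  # disjoint union equal to the input
  all_ids <- sort(unname(unlist(lapply(parts, `[[`, "id"))))
  expect_equal(all_ids, sort(cohort$id))
  # per-cell largest-remainder guarantee
  for (s in c("F", "M")) {
    cell_n <- sum(cohort$sex == s)
    got <- vapply(parts, function(p) sum(p$sex == s), 0L)
    expect_true(all(abs(got - c(0.44, 0.24, 0.32) * cell_n) <= 1))
  }
  all_in_first <- stratified_partition(cohort, c(1, 0, 0), strata = "sex")
  expect_equal(nrow(all_in_first$development), 100)
  expect_equal(nrow(all_in_first$external), 0)
  expect_error(stratified_partition(cohort, c(0.5, 0.5, 0.5)), "summing")
  expect_error(stratified_partition(cohort, strata = "no_such"), "stratum")
  empty <- stratified_partition(cohort[0, ], strata = "sex")
  expect_equal(nrow(empty$development), 0)
})

test_that("end-to-end: generator, fitter and evaluator close the loop", {
  # markers generated, mGFR re-simulated from the published structure with a
  # single branch, then the structure refitted: coefficients must come back
  cohort <- generate_cohort(cohort_config(n = 2000, seed = 1))
  cfg <- gfr_equation_coefficients("gfr_nmr")
  for (i in 1:4) {
    cfg$branches[[i]]$intercept <- 238
    cfg$branches[[i]]$pivot_exponent <- -0.4114
  }
  cohort <- simulate_mgfr(cohort, cfg, sigma_log = 0.1, seed = 101)
  f <- model_formula(c("log(cystatin_c)", "log(creatinine)", "log(valine)",
                       "myo_inositol", "age"), response = "log")
  cand <- fit_formula(f, cohort)
  truth <- c(log(238), -0.4114, -0.3798, 0.1628, log(0.9979), log(0.9963))
  z <- (coef(cand) - truth) / cand$se
  expect_true(all(abs(z) < 3))
})
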