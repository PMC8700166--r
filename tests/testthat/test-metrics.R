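test_that("error summary matches hand-computed values", {
  es <- error_summary(c(50, 60, 70, 90), c(55, 60, 65, 80))
  expect_equal(es$median_bias, 2.5)
  expect_equal(es$mae, 5.0)
  expect_equal(es$iqr_precision, 7.5)  # type-7 quartiles -1.25 and 6.25

  perfect <- error_summary(c(40, 80), c(40, 80))
  expect_equal(unlist(perfect), c(median_bias = 0, iqr_precision = 0,
                                  mae = 0, rmsle = 0))

  single <- error_summary(60, 50)
  expect_equal(single$median_bias, 10)
  expect_equal(single$iqr_precision, 0)
  expect_equal(single$mae, 10)
  expect_error(error_summary(numeric(0), numeric(0)), "empty")
})

test_that("accuracy outside tolerance treats the boundary as within", {
  mg <- rep(100, 4)
  eg <- c(85, 79, 131, 100)
  expect_equal(accuracy_outside(eg, mg, 15), 50)
  expect_equal(accuracy_outside(eg, mg, 20), 50)
  expect_equal(accuracy_outside(eg, mg, 30), 25)
  expect_equal(accuracy_outside(mg, mg, 15), 0)
})

test_that("accuracy is non-increasing in the tolerance", {
  set.seed(5)
  mg <- runif(200, 10, 150)
  eg <- mg * exp(rnorm(200, 0, 0.3))
  vals <- vapply(c(15, 20, 30), function(x) accuracy_outside(eg, mg, x), 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("REC curve is non-decreasing and consistent with 1-Px", {
  set.seed(6)
  mg <- runif(100, 20, 120)
  eg <- mg + rnorm(100, 0, 15)
  curve <- rec_curve(eg, mg, grid = c(5, 10, 15, 20, 30, 50))
  expect_true(all(diff(curve$px_pct) >= 0))
  for (x in c(15, 20, 30)) {
    expect_equal(curve$px_pct[curve$tolerance_pct == x],
                 100 - accuracy_outside(eg, mg, x))
  }
  ident <- rec_curve(mg, mg, grid = c(10, 20))
  expect_equal(ident$px_pct, c(100, 100))
  expect_error(rec_curve(eg, mg, grid = numeric(0)), "empty")
})

test_that("metrics are permutation invariant and bias is translation covariant", {
  set.seed(7)
  mg <- runif(80, 20, 120)
  eg <- mg + rnorm(80, 0, 12)
  perm <- sample(80)
  expect_equal(error_summary(eg, mg)$iqr_precision,
               error_summary(eg[perm], mg[perm])$iqr_precision)
  expect_equal(accuracy_outside(eg, mg, 20),
               accuracy_outside(eg[perm], mg[perm], 20))
  shifted <- error_summary(eg + 7, mg)
  expect_equal(shifted$median_bias, error_summary(eg, mg)$median_bias + 7)
})

test_that("bootstrap CI is seeded, deterministic and degenerate-safe", {
  stat <- function(e, m) median(e - m)
  mg <- runif(60, 30, 110)
  eg <- mg + 5  # constant difference
  ci <- bootstrap_ci(stat, eg, mg, n_boot = 100, seed = 3)
  expect_equal(ci$ci_low, 5)
  expect_equal(ci$ci_high, 5)
  expect_equal(ci$estimate, 5)

  set.seed(11)
  eg2 <- mg + rnorm(60, 0, 8)
  a <- bootstrap_ci(stat, eg2, mg, n_boot = 300, seed = 17)
  b <- bootstrap_ci(stat, eg2, mg, n_boot = 300, seed = 17)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$estimate)
  expect_gte(a$ci_high, a$estimate)
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  stat <- function(e, m) median(e - m)
  width <- function(n, seed) {
    set.seed(seed)
    mg <- runif(n, 30, 110)
    eg <- mg + rnorm(n, 0, 10)
    ci <- bootstrap_ci(stat, eg, mg, n_boot = 500, seed = 1)
    ci$ci_high - ci$ci_low
  }
  w100 <- mean(vapply(1:5, function(s) width(100, s), 0))
  w400 <- mean(vapply(6:10, function(s) width(400, s), 0))
  expect_lt(w400, w100)                 # must shrink
  expect_equal(w100 / w400, 2, tolerance = 0.5)  # ~sqrt(4)
})

test_that("paired comparisons: degenerate, closed-form and shifted cases", {
  set.seed(21)
  mg <- runif(50, 20, 120)
  eg <- mg + rnorm(50, 0, 10)
  expect_message(
    same <- compare_equations(eg, eg, mg, n_boot = 100, seed = 2),
    "convention")
  expect_true(all(unlist(same) == 1))

  # McNemar with discordant counts 10 vs 0: (|10-0|-1)^2/10 = 8.1
  mg2 <- rep(100, 30)
  eg_a <- c(rep(130, 10), rep(100, 20))  # 10 outside 15%, rest exact
  eg_b <- rep(100, 30)
  suppressMessages(
    cmp <- compare_equations(eg_a, eg_b, mg2, tolerances = 15,
                             n_boot = 100, seed = 2))
  expect_equal(cmp$p_p15, pchisq(8.1, df = 1, lower.tail = FALSE))
  expect_equal(cmp$p_p15, 0.0044, tolerance = 1e-2)

  # constant shift of all signed errors: Wilcoxon must reject
  shifted <- compare_equations(eg + 5, eg, mg, n_boot = 100, seed = 2)
  expect_lt(shifted$p_bias, 0.001)

  expect_error(compare_equations(eg[-1], eg, mg), "mismatch|equal length")
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  p <- c(0.005, 0.04, 0.03, 0.8)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))               # never decreases a p-value
  expect_true(all(bh_adjust(adj) >= adj))  # re-adjusting cannot decrease
  expect_equal(bh_adjust(rep(0.2, 3)), rep(0.2, 3))  # constant fixed point
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evaluation report has the benchmark-table layout", {
  cohort <- generate_cohort(cohort_config(n = 120, seed = 31))
  rep1 <- evaluate_equations(cohort, equations = c("gfr_nmr", "ekfc"),
                             n_boot = 50, seed = 1)
  expect_setequal(unique(rep1$equation), c("gfr_nmr", "ekfc"))
  expect_setequal(unique(rep1$metric),
                  c("median_bias", "iqr_precision", "mae", "rmsle",
                    "outside_p15", "outside_p20", "outside_p30"))
  expect_true(all(rep1$ci_low <= rep1$estimate + 1e-12))
  expect_true(all(rep1$ci_high >= rep1$estimate - 1e-12))
  expect_true(all(rep1$n == 120))

  by_range <- evaluate_equations(cohort, equations = "gfr_nmr",
                                 by_egfr_range = TRUE, n_boot = 20, seed = 1)
  expect_true("overall" %in% by_range$subgroup)
  expect_gt(length(unique(by_range$subgroup)), 1)

  pw <- compare_to_reference(cohort, reference = "gfr_nmr",
                             equations = c("ekfc", "ckd_epi_2009"),
                             n_boot = 50, seed = 1)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))
  expect_setequal(unique(pw$equation), c("ekfc", "ckd_epi_2009"))
})
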