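test_that("noiseless generating model is recovered exactly", {
  d <- noiseless_cohort()
  f <- model_formula(c("log(a)", "log(b)", "c"), response = "log")
  cand <- fit_formula(f, d)
  expect_equal(unname(coef(cand)), c(4, -0.5, 0.3, -0.01), tolerance = 1e-8)
  expect_lt(cand$train_mae, 1e-8)
  expect_equal(cand$train_p30, 100)
})

test_that("rank-deficient designs raise a collinearity error", {
  d <- noiseless_cohort()
  d$a2 <- d$a  # duplicated predictor under the same transform
  f <- model_formula(c("log(a)", "log(a2)", "c"), response = "log")
  expect_error(fit_formula(f, d), "collinear")
  expect_error(fit_formula(model_formula(c("log(a)", "log(b)")),
                           noiseless_cohort(n = 3)), "insufficient")
})

test_that("raw-response OLS residuals are orthogonal to the design", {
  set.seed(13)
  d <- noiseless_cohort(n = 100)
  d$mgfr <- d$mgfr + rnorm(100, 0, 3)
  f <- model_formula(c("log(a)", "log(b)", "c"), response = "raw")
  cand <- fit_formula(f, d)
  res <- residuals(cand, type = "response")
  for (col in list(rep(1, 100), log(d$a), log(d$b), d$c)) {
    expect_lt(abs(sum(res * col)) / 100, 1e-8)
  }
})

test_that("candidate methods behave like a classed model fit", {
  set.seed(14)
  d <- noiseless_cohort(n = 80)
  d$mgfr <- d$mgfr * exp(rnorm(80, 0, 0.1))
  f <- model_formula(c("log(a)", "log(b)", "c"), response = "log")
  cand <- fit_formula(f, d)
  expect_output(print(cand), "Candidate equation")
  expect_output(print(summary(cand)), "Std. Error")
  expect_equal(predict(cand, d), fitted(cand))
  expect_equal(residuals(cand), fitted(cand) - d$mgfr)
  sims <- simulate(cand, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(80L, 3L))
  expect_identical(sims, simulate(cand, nsim = 3, seed = 5))
})

test_that("cross-validation is seeded, deterministic and near zero without noise", {
  d <- noiseless_cohort(n = 120)
  f <- model_formula(c("log(a)", "log(b)", "c"), response = "log")
  cv1 <- cross_validate(f, d, seed = 7)
  cv2 <- cross_validate(f, d, seed = 7)
  expect_identical(cv1, cv2)
  expect_lt(cv1$cv_mae_mean, 1e-8)
  expect_equal(length(cv1$fold_mae), 25)
  cv3 <- cross_validate(f, d, seed = 8)
  expect_false(identical(cv1$fold_mae, cv3$fold_mae))
  cand <- cross_validate(fit_formula(f, d), d, seed = 7)
  expect_equal(cand$cv_mae_mean, cv1$cv_mae_mean)
  expect_error(cross_validate(f, d[1:10, ], folds = 5), "too few")
})

test_that("CV MAE approximates the theoretical error of the true model", {
  # raw response with gaussian noise: E|error| = sigma * sqrt(2/pi)
  set.seed(15)
  n <- 600
  sigma <- 5
  d <- data.frame(a = runif(n, 1, 10), b = runif(n, 1, 10))
  d$mgfr <- 40 + 3 * d$a + 2 * d$b + rnorm(n, 0, sigma)
  f <- model_formula(c("a", "b"), response = "raw")
  cv <- cross_validate(f, d, seed = 2)
  theoretical <- sigma * sqrt(2 / pi)
  expect_equal(cv$cv_mae_mean, theoretical, tolerance = 0.2)
})

test_that("Vuong test flags the better model and degenerates safely", {
  set.seed(16)
  n <- 500
  d <- data.frame(a = exp(rnorm(n)), b = exp(rnorm(n)))
  d$mgfr <- exp(3 + 0.5 * log(d$a) - 0.6 * log(d$b) + rnorm(n, 0, 0.15))
  full <- fit_formula(model_formula(c("log(a)", "log(b)"), response = "log"), d)
  reduced <- fit_formula(model_formula(c("log(a)", "b"), response = "log"), d)
  v <- vuong_test(full, reduced)
  expect_gt(v$statistic, 0)
  expect_lt(v$p, 0.05)
  expect_warning(same <- vuong_test(full, full), "undefined")
  expect_equal(same$p, 1)
  expect_true(is.na(same$statistic))
})

test_that("Vuong statistic matches a hand-evaluated small example", {
  d <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  d$mgfr <- c(50, 60, 70, 80, 90)
  ca <- fit_formula(model_formula(c("a", "b"), response = "raw"), d)
  cb <- fit_formula(model_formula(c("a", "log(b)"), response = "raw"), d)
  ll <- function(res) {
    s <- sqrt(mean(res^2))
    dnorm(res, 0, s, log = TRUE)
  }
  m <- ll(residuals(ca, "response")) - ll(residuals(cb, "response"))
  by_hand <- sqrt(5) * mean(m) / sd(m)
  v <- vuong_test(ca, cb)
  expect_equal(v$statistic, by_hand)
  expect_equal(v$p, 2 * pnorm(-abs(by_hand)))
})

test_that("Vuong test favours the true model in most simulations", {
  wins <- 0L
  n_sim <- 40L
  for (s in seq_len(n_sim)) {
    set.seed(700 + s)
    n <- 500
    d <- data.frame(a = exp(rnorm(n)), b = exp(rnorm(n)), c = runif(n, 1, 2))
    d$mgfr <- exp(3 + 0.5 * log(d$a) - 0.5 * log(d$b) + rnorm(n, 0, 0.2))
    true_fit <- fit_formula(model_formula(c("log(a)", "log(b)"),
                                          response = "log"), d)
    # same size model missing the strong predictor b
    missing_fit <- fit_formula(model_formula(c("log(a)", "c"),
                                             response = "log"), d)
    v <- vuong_test(true_fit, missing_fit)
    if (!is.na(v$statistic) && v$statistic > 0 && v$p < 0.05) wins <- wins + 1L
  }
  expect_gt(wins / n_sim, 0.9)
})
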