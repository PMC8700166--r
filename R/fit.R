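# Resolve a formula parameter to a cohort column (bare name first, then the
# canonical schema aliases).
.resolve_param <- function(cohort, parameter) {
  if (parameter %in% names(cohort)) return(cohort[[parameter]])
  if (parameter %in% names(.marker_aliases)) {
    col <- .find_column(cohort, parameter)
    if (!is.null(col)) return(cohort[[col]])
  }
  stop("cohort is missing parameter: ", parameter, call. = FALSE)
}

.term_column <- function(cohort, parameter, transform) {
  x <- .resolve_param(cohort, parameter)
  if (anyNA(x)) stop("parameter '", parameter, "' contains NA", call. = FALSE)
  if (transform == "log") {
    if (any(x <= 0)) stop("cannot log-transform non-positive '", parameter, "'",
                          call. = FALSE)
    log(x)
  } else x
}

# Design matrix (without intercept) implied by a gfr_formula.
.design_matrix <- function(formula, cohort) {
  terms <- .term_string(formula$mains$parameter, formula$mains$transform)
  cols <- lapply(seq_len(nrow(formula$mains)), function(i) {
    .term_column(cohort, formula$mains$parameter[i], formula$mains$transform[i])
  })
  if (!is.null(formula$interaction)) {
    it <- formula$interaction
    cols[[length(cols) + 1L]] <-
      .term_column(cohort, it$parameter[1], it$transform[1]) *
      .term_column(cohort, it$parameter[2], it$transform[2])
    terms <- c(terms, paste(.term_string(it$parameter[1], it$transform[1]),
                            .term_string(it$parameter[2], it$transform[2]),
                            sep = ":"))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

.response_vector <- function(formula, cohort) {
  mgfr <- .get_marker(cohort, "mgfr")
  if (formula$response == "log") log(mgfr) else mgfr
}

.back_transform <- function(formula, yhat) {
  if (formula$response == "log") exp(yhat) else yhat
}

.ols <- function(X, y) {
  X1 <- cbind(`(intercept)` = 1, X)
  qrX <- qr(X1)
  if (qrX$rank < ncol(X1)) {
    stop("collinear design: rank ", qrX$rank, " < ", ncol(X1), " columns",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X1 %*% beta)
  res <- y - fitted
  n <- length(y); p <- ncol(X1)
  sigma2 <- sum(res^2) / (n - p)
  R <- qr.R(qrX)
  Rinv <- backsolve(R, diag(p))
  covb <- sigma2 * tcrossprod(Rinv)
  # undo qr pivoting in the covariance ordering
  piv <- qrX$pivot
  se <- setNames(numeric(p), colnames(X1))
  se[piv] <- sqrt(diag(covb))
  list(coefficients = beta, se = se, fitted = fitted, residuals = res,
       sigma = sqrt(sigma2), df_residual = n - p)
}

#' Fit a candidate formula by ordinary least squares
#'
#' Trains the model implied by a [model_formula()] on a cohort (response:
#' mGFR or natural-log mGFR). Predictions are back-transformed to the GFR
#' scale (plain exponentiation for the log response, no smearing
#' correction) before any performance indicator is computed.
#'
#' @param formula A `gfr_formula`.
#' @param cohort Data frame with the formula's parameters and measured GFR.
#' @return An object of class `gfr_candidate` with components including
#'   `coefficients`, `se`, `train_mae`, `train_p15/p20/p30` (percentage of
#'   training samples within 15/20/30% of mGFR), `heteroscedasticity`
#'   (absolute Spearman correlation of |residual| with fitted values on the
#'   response scale) and `upper_range_reach` (fraction of samples with
#'   mGFR >= 90 predicted >= 90; `NA` if no such samples). Cross-validation
#'   statistics are `NA` until [cross_validate()] is run.
#' @seealso [cross_validate()], [apply_filters()], [engineer_piecewise()]
#' @export
fit_formula <- function(formula, cohort) {
  stopifnot(inherits(formula, "gfr_formula"))
  X <- .design_matrix(formula, cohort)
  y <- .response_vector(formula, cohort)
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("insufficient samples: n = ", n, " for ",
                              ncol(X), " features")
  fit <- .ols(X, y)
  mgfr <- .get_marker(cohort, "mgfr")
  pred <- .back_transform(formula, fit$fitted)
  abs_err <- abs(pred - mgfr)
  within <- function(x) 100 * mean(abs_err <= (x / 100) * mgfr)
  high <- mgfr >= 90
  het <- if (sd(abs(fit$residuals)) == 0 || sd(fit$fitted) == 0) 0 else
    abs(cor(abs(fit$residuals), fit$fitted, method = "spearman"))
  structure(list(
    formula = formula,
    coefficients = fit$coefficients, se = fit$se,
    sigma = fit$sigma, df_residual = fit$df_residual, n = n,
    fitted_response = fit$fitted, residuals_response = fit$residuals,
    fitted_gfr = pred, mgfr = mgfr,
    train_mae = mean(abs_err),
    train_p15 = within(15), train_p20 = within(20), train_p30 = within(30),
    heteroscedasticity = het,
    upper_range_reach = if (any(high)) mean(pred[high] >= 90) else NA_real_,
    cv_mae_mean = NA_real_, cv_mae_cv = NA_real_, cv_fold_mae = NULL
  ), class = "gfr_candidate")
}

#' @export
print.gfr_candidate <- function(x, ...) {
  cat("Candidate equation:", format(x$formula), "\n")
  cat(sprintf("  n = %d, train MAE = %.2f, P30 = %.1f%%, P20 = %.1f%%\n",
              x$n, x$train_mae, x$train_p30, x$train_p20))
  if (!is.na(x$cv_mae_mean)) {
    cat(sprintf("  CV MAE = %.2f (CV of fold MAEs = %.3f)\n",
                x$cv_mae_mean, x$cv_mae_cv))
  }
  invisible(x)
}

#' @export
coef.gfr_candidate <- function(object, ...) object$coefficients

#' @export
summary.gfr_candidate <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(formula = object$formula, coefficients = tab,
                 sigma = object$sigma, n = object$n,
                 train_mae = object$train_mae, train_p30 = object$train_p30,
                 heteroscedasticity = object$heteroscedasticity,
                 upper_range_reach = object$upper_range_reach,
                 cv_mae_mean = object$cv_mae_mean, cv_mae_cv = object$cv_mae_cv),
            class = "summary.gfr_candidate")
}

#' @export
print.summary.gfr_candidate <- function(x, ...) {
  cat("Candidate equation:", format(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual sigma (response scale): %.4f on n = %d\n", x$sigma, x$n))
  cat(sprintf("Training MAE %.2f, P30 %.1f%%, heteroscedasticity %.3f\n",
              x$train_mae, x$train_p30, x$heteroscedasticity))
  if (!is.na(x$cv_mae_mean)) {
    cat(sprintf("CV MAE %.2f (fold CV %.3f)\n", x$cv_mae_mean, x$cv_mae_cv))
  }
  invisible(x)
}

#' @export
predict.gfr_candidate <- function(object, newdata, ...) {
  X <- .design_matrix(object$formula, newdata)
  yhat <- drop(cbind(1, X) %*% object$coefficients)
  .back_transform(object$formula, yhat)
}

#' @export
residuals.gfr_candidate <- function(object, type = c("gfr", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals_response
  else object$fitted_gfr - object$mgfr
}

#' @export
fitted.gfr_candidate <- function(object, ...) object$fitted_gfr

#' @export
simulate.gfr_candidate <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  sig <- object$sigma
  out <- replicate(nsim, .back_transform(
    object$formula, object$fitted_response + rnorm(object$n, 0, sig)))
  as.data.frame(out)
}

#' @export
plot.gfr_candidate <- function(x, ...) {
  plot(x$fitted_response, x$residuals_response,
       xlab = "Fitted (response scale)", ylab = "Residual",
       main = format(x$formula), ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' Repeated k-fold cross-validation of a candidate formula
#'
#' Performs `repeats` rounds of `folds`-fold cross-validation with a seeded
#' shuffled fold assignment per round. Fold MAEs are computed out of sample
#' on the GFR scale (back-transformed for the log response). The summary is
#' the mean of the fold MAEs and their coefficient of variation (sd/mean),
#' the stability indicator used by the filtering pipeline.
#'
#' @param x A `gfr_formula` or a fitted `gfr_candidate`.
#' @param cohort Training cohort.
#' @param repeats,folds Cross-validation layout (5 x 5 in routine use).
#' @param seed Integer seed; identical seeds give identical fold
#'   assignments.
#' @param stratify_by Optional cohort column name; fold assignment is then
#'   shuffled within the levels of that column.
#' @return For a formula: list with `cv_mae_mean`, `cv_mae_cv`,
#'   `fold_mae`. For a candidate: the candidate with those fields filled.
#' @export
cross_validate <- function(x, cohort, repeats = 5, folds = 5, seed = 1,
                           stratify_by = NULL) {
  formula <- if (inherits(x, "gfr_candidate")) x$formula else x
  stopifnot(inherits(formula, "gfr_formula"))
  X <- .design_matrix(formula, cohort)
  y <- .response_vector(formula, cohort)
  mgfr <- .get_marker(cohort, "mgfr")
  n <- length(y)
  p <- ncol(X)
  if (n < folds * (p + 2L)) {
    stop("too few samples for ", folds, "-fold CV with ", p, " features")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  strata <- if (is.null(stratify_by)) rep(1L, n) else {
    if (!stratify_by %in% names(cohort)) stop("unknown stratum column: ", stratify_by)
    as.integer(factor(cohort[[stratify_by]]))
  }
  fold_mae <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold_id[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (sum(!test) <= p + 1L) stop("fold too small to fit the model")
      fit <- .ols(X[!test, , drop = FALSE], y[!test])
      yhat <- drop(cbind(1, X[test, , drop = FALSE]) %*% fit$coefficients)
      pred <- .back_transform(formula, yhat)
      fold_mae <- c(fold_mae, mean(abs(pred - mgfr[test])))
    }
  }
  m <- mean(fold_mae)
  res <- list(cv_mae_mean = m,
              cv_mae_cv = if (m == 0) 0 else sd(fold_mae) / m,
              fold_mae = fold_mae)
  if (inherits(x, "gfr_candidate")) {
    x$cv_mae_mean <- res$cv_mae_mean
    x$cv_mae_cv <- res$cv_mae_cv
    x$cv_fold_mae <- res$fold_mae
    return(x)
  }
  res
}

#' Vuong test for comparing two candidate equations
#'
#' Classical Vuong statistic for (possibly non-nested) model comparison:
#' the mean pointwise log-likelihood difference over its standard error,
#' scaled by sqrt(n), referred to the standard normal (two-sided).
#' Pointwise Gaussian log-likelihoods are formed from each model's
#' maximum-likelihood residual variance on the shared response scale.
#' Positive statistics favour `candidate_a`.
#'
#' @param candidate_a,candidate_b Fitted `gfr_candidate` objects trained on
#'   the same samples with the same response transform.
#' @return List with `statistic` and `p` (two-sided). If the pointwise
#'   log-likelihood differences have zero variance the statistic is
#'   undefined and reported as non-significant with a warning.
#' @export
vuong_test <- function(candidate_a, candidate_b) {
  stopifnot(inherits(candidate_a, "gfr_candidate"),
            inherits(candidate_b, "gfr_candidate"))
  if (candidate_a$n != candidate_b$n) stop("candidates fitted on different n")
  if (candidate_a$formula$response != candidate_b$formula$response) {
    stop("candidates must share the response transform")
  }
  ll <- function(cand) {
    s <- sqrt(mean(cand$residuals_response^2))  # MLE sigma
    dnorm(cand$residuals_response, 0, s, log = TRUE)
  }
  m <- ll(candidate_a) - ll(candidate_b)
  if (sd(m) == 0) {
    warning("identical pointwise log-likelihoods; Vuong statistic undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p = 1))
  }
  stat <- sqrt(length(m)) * mean(m) / sd(m)
  list(statistic = stat, p = 2 * pnorm(-abs(stat)))
}
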