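.check_pairs <- function(egfr, mgfr) {
  if (length(egfr) == 0L || length(mgfr) == 0L) stop("empty prediction pairs")
  if (length(egfr) != length(mgfr)) stop("egfr and mgfr must have equal length")
  if (anyNA(egfr) || anyNA(mgfr)) stop("prediction pairs contain NA")
  if (any(mgfr <= 0)) stop("mgfr must be strictly positive")
  invisible(TRUE)
}

#' Error summary for paired eGFR/mGFR predictions
#'
#' Differences are taken as eGFR - mGFR, so that underestimation of the
#' measured GFR yields a negative bias. Quartiles use type-7 linear
#' interpolation (the default quantile definition of R).
#'
#' @param egfr,mgfr Aligned numeric vectors, mL/min/1.73 m^2; `mgfr` > 0.
#' @return Named list with `median_bias` (median of the differences),
#'   `iqr_precision` (Q3 - Q1 of the differences), `mae` (mean absolute
#'   difference) and `rmsle` (root mean squared difference of log1p values).
#' @examples
#' error_summary(c(50, 60, 70, 90), c(55, 60, 65, 80))
#' @export
error_summary <- function(egfr, mgfr) {
  .check_pairs(egfr, mgfr)
  d <- egfr - mgfr
  q <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  list(
    median_bias = median(d),
    iqr_precision = q[2] - q[1],
    mae = mean(abs(d)),
    rmsle = sqrt(mean((log1p(egfr) - log1p(mgfr))^2))
  )
}

#' Percentage of predictions outside an x% tolerance (1-Px)
#'
#' 1-Px is the percentage of samples whose eGFR deviates from mGFR by more
#' than x% of mGFR; a deviation exactly at the boundary counts as within.
#'
#' @inheritParams error_summary
#' @param x Tolerance in percent, > 0 (15, 20 and 30 in routine reporting).
#' @return Percentage in \[0, 100\].
#' @export
accuracy_outside <- function(egfr, mgfr, x) {
  .check_pairs(egfr, mgfr)
  if (!is.numeric(x) || length(x) != 1L || x <= 0) stop("x must be a positive scalar")
  100 * mean(abs(egfr - mgfr) > (x / 100) * mgfr)
}

#' Regression error characteristic (REC) curve
#'
#' Px(x) = 100 - (1-Px), the percentage of predictions within x% of mGFR,
#' evaluated on a grid of tolerances; non-decreasing in x.
#'
#' @inheritParams error_summary
#' @param grid Ascending positive tolerances in percent.
#' @return A data frame with columns `tolerance_pct` and `px_pct`.
#' @export
rec_curve <- function(egfr, mgfr, grid = 1:50) {
  if (length(grid) == 0L) stop("empty tolerance grid")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly ascending and positive")
  }
  px <- vapply(grid, function(x) 100 - accuracy_outside(egfr, mgfr, x), 0)
  data.frame(tolerance_pct = grid, px_pct = px)
}

#' Percentile bootstrap confidence interval for a paired-prediction statistic
#'
#' Resamples whole (eGFR, mGFR) pairs with replacement and returns the
#' percentile interval of the replicate statistics. Deterministic given
#' `seed`. Replicates on which the statistic fails or is NA are skipped with
#' a warning; more than 10% skipped replicates is an error.
#'
#' @param statistic Function of `(egfr, mgfr)` returning a scalar.
#' @inheritParams error_summary
#' @param n_boot Number of bootstrap replicates (1000 in routine use).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `n_boot_used`.
#' @examples
#' set.seed(1)
#' m <- runif(50, 30, 120); e <- m + rnorm(50, 0, 8)
#' bootstrap_ci(function(e, m) median(e - m), e, m, n_boot = 200, seed = 42)
#' @export
bootstrap_ci <- function(statistic, egfr, mgfr, n_boot = 1000, seed = 1,
                         conf = 0.95) {
  .check_pairs(egfr, mgfr)
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- length(egfr)
  est <- statistic(egfr, mgfr)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(statistic(egfr[idx], mgfr[idx]),
                        error = function(e) NA_real_)
  }
  skipped <- sum(is.na(reps))
  if (skipped > 0) {
    warning(skipped, " bootstrap replicate(s) skipped", call. = FALSE)
    if (skipped > 0.1 * n_boot) {
      stop("more than 10% of bootstrap replicates failed")
    }
    reps <- reps[!is.na(reps)]
  }
  a <- (1 - conf) / 2
  ci <- quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = est, ci_low = ci[1], ci_high = ci[2],
       n_boot_used = n_boot - skipped)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Paired significance tests between two eGFR equations
#'
#' Both equations must be evaluated on the same samples against the same
#' mGFR. Bias and MAE differences use the two-sided paired Wilcoxon
#' signed-rank test on per-sample signed-error (respectively
#' absolute-error) differences; accuracy differences at each tolerance use
#' McNemar's test on the paired within/outside indicators
#' (continuity-corrected by default, exact binomial optionally); the IQR
#' difference uses a two-sided percentile bootstrap test (twice the
#' fraction of replicate differences on the minority side of zero).
#'
#' @param egfr_a,egfr_b eGFR vectors of the two equations on the same samples.
#' @param mgfr Measured GFR vector.
#' @param tolerances Accuracy tolerances in percent.
#' @param n_boot,seed Bootstrap settings for the IQR test.
#' @param exact_mcnemar Use the exact binomial McNemar variant.
#' @return Named list of p-values: `p_bias`, `p_mae`, `p_iqr`, and one
#'   `p_p<x>` per tolerance.
#' @export
compare_equations <- function(egfr_a, egfr_b, mgfr, tolerances = c(15, 20, 30),
                              n_boot = 1000, seed = 1, exact_mcnemar = FALSE) {
  .check_pairs(egfr_a, mgfr)
  .check_pairs(egfr_b, mgfr)
  if (length(egfr_a) != length(egfr_b)) stop("mismatched samples")
  da <- egfr_a - mgfr
  db <- egfr_b - mgfr

  wilcox_p <- function(diffs) {
    if (all(diffs == 0)) {
      message("all paired differences are zero; p = 1 by convention")
      return(1)
    }
    suppressWarnings(wilcox.test(diffs, mu = 0, exact = FALSE)$p.value)
  }
  mcnemar_p <- function(x) {
    out_a <- abs(da) > (x / 100) * mgfr
    out_b <- abs(db) > (x / 100) * mgfr
    b <- sum(out_a & !out_b)
    c <- sum(!out_a & out_b)
    if (b + c == 0) {
      message("no discordant accuracy pairs at ", x, "%; p = 1 by convention")
      return(1)
    }
    if (exact_mcnemar) return(binom.test(b, b + c, 0.5)$p.value)
    stat <- (abs(b - c) - 1)^2 / (b + c)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  iqr_boot_p <- function() {
    iqr <- function(d) {
      q <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7); q[2] - q[1]
    }
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    n <- length(mgfr)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      iqr(da[idx]) - iqr(db[idx])
    }, 0)
    if (all(reps == 0)) return(1)
    min(1, 2 * min(mean(reps <= 0), mean(reps >= 0)))
  }

  out <- list(p_bias = wilcox_p(da - db),
              p_mae = wilcox_p(abs(da) - abs(db)),
              p_iqr = iqr_boot_p())
  for (x in tolerances) out[[paste0("p_p", x)]] <- mcnemar_p(x)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Metric report for one or more equations on a cohort
#'
#' Builds a long-format validation report (one row per equation x subgroup x
#' metric) with percentile bootstrap confidence intervals: median bias, IQR
#' precision, MAE, RMSLE and the 1-P15/20/30 accuracy metrics.
#'
#' @param cohort Cohort data frame containing mGFR and either pre-computed
#'   `egfr_<equation>_ml_min_173` columns or the markers needed to compute
#'   them (see [estimate_gfr()]).
#' @param equations Equation ids to evaluate.
#' @param group_by Optional name of a cohort column defining subgroups; each
#'   subgroup is reported in addition to "overall".
#' @param by_egfr_range If `TRUE`, subgroups are the eGFR ranges
#'   (<15, 15-29, 30-59, 60-89, >=90), each equation binned by its own
#'   estimate.
#' @param tolerances Accuracy tolerances in percent.
#' @param n_boot,seed,conf Bootstrap settings (see [bootstrap_ci()]).
#' @return Data frame with columns `equation`, `subgroup`, `metric`, `unit`,
#'   `n`, `estimate`, `ci_low`, `ci_high`.
#' @export
evaluate_equations <- function(cohort, equations = gfr_equations(),
                               group_by = NULL, by_egfr_range = FALSE,
                               tolerances = c(15, 20, 30),
                               n_boot = 1000, seed = 1, conf = 0.95) {
  mgfr <- .get_marker(cohort, "mgfr")
  cohort <- estimate_gfr(cohort, setdiff(
    equations, sub("^egfr_(.*)_ml_min_173$", "\\1", names(cohort))))
  metrics <- c(median_bias = "mL/min/1.73m2", iqr_precision = "mL/min/1.73m2",
               mae = "mL/min/1.73m2", rmsle = "log scale")
  stats <- list(
    median_bias = function(e, m) median(e - m),
    iqr_precision = function(e, m) {
      q <- quantile(e - m, c(0.25, 0.75), names = FALSE, type = 7); q[2] - q[1]
    },
    mae = function(e, m) mean(abs(e - m)),
    rmsle = function(e, m) sqrt(mean((log1p(e) - log1p(m))^2))
  )
  for (x in tolerances) {
    id <- paste0("outside_p", x)
    metrics[id] <- "%"
    stats[[id]] <- local({
      xx <- x
      function(e, m) 100 * mean(abs(e - m) > (xx / 100) * m)
    })
  }
  rows <- list()
  for (eq in equations) {
    e <- cohort[[paste0("egfr_", eq, "_ml_min_173")]]
    groups <- list(overall = rep(TRUE, length(mgfr)))
    if (by_egfr_range) {
      # per-equation binning by the equation's own estimate
      br <- cut(e, c(0, 15, 30, 60, 90, Inf), right = FALSE,
                labels = c("<15", "15-29", "30-59", "60-89", ">=90"))
      for (lv in levels(br)) groups[[paste0("egfr ", lv)]] <- br == lv
    } else if (!is.null(group_by)) {
      if (!group_by %in% names(cohort)) stop("unknown grouping column: ", group_by)
      g <- cohort[[group_by]]
      for (lv in unique(g)) groups[[paste(group_by, lv)]] <- g == lv
    }
    for (gname in names(groups)) {
      sel <- groups[[gname]]
      if (!any(sel)) next
      for (mid in names(stats)) {
        ci <- bootstrap_ci(stats[[mid]], e[sel], mgfr[sel],
                           n_boot = n_boot, seed = seed, conf = conf)
        rows[[length(rows) + 1L]] <- data.frame(
          equation = eq, subgroup = gname, metric = mid,
          unit = unname(metrics[mid]), n = sum(sel),
          estimate = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pairwise comparison table against a reference equation
#'
#' Runs [compare_equations()] of every other equation against the reference
#' and adjusts p-values across equations within each test family
#' (Benjamini-Hochberg).
#'
#' @inheritParams evaluate_equations
#' @param reference Equation id all others are tested against.
#' @return Data frame with one row per (equation, test) and columns
#'   `p_value`, `p_adjusted`.
#' @export
compare_to_reference <- function(cohort, reference = "gfr_nmr",
                                 equations = setdiff(gfr_equations(), reference),
                                 tolerances = c(15, 20, 30),
                                 n_boot = 1000, seed = 1) {
  mgfr <- .get_marker(cohort, "mgfr")
  cohort <- estimate_gfr(cohort, setdiff(
    union(reference, equations),
    sub("^egfr_(.*)_ml_min_173$", "\\1", names(cohort))))
  ref <- cohort[[paste0("egfr_", reference, "_ml_min_173")]]
  out <- list()
  for (eq in equations) {
    p <- compare_equations(ref, cohort[[paste0("egfr_", eq, "_ml_min_173")]],
                           mgfr, tolerances = tolerances,
                           n_boot = n_boot, seed = seed)
    out[[eq]] <- data.frame(equation = eq, test = names(p),
                            p_value = unlist(p), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  # BH within each test family, across the compared equations
  tab$p_adjusted <- NA_real_
  for (tst in unique(tab$test)) {
    i <- tab$test == tst
    tab$p_adjusted[i] <- bh_adjust(tab$p_value[i])
  }
  tab
}
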