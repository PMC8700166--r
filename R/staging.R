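.stage_levels <- c("G5", "G4", "G3b", "G3a", "G2", "G1")

#' KDIGO CKD stage from GFR
#'
#' Stages are assigned on the unrounded GFR value by half-open intervals
#' partitioning (0, Inf): G1 \[90, Inf), G2 \[60, 90), G3a \[45, 60),
#' G3b \[30, 45), G4 \[15, 30), G5 (0, 15).
#'
#' @param gfr Numeric vector of GFR values, mL/min/1.73 m^2, > 0.
#' @param coarse If `TRUE`, merge G3a/G3b into a single G3 category.
#' @return Factor of stage labels, ordered from G5 (lowest GFR) to G1.
#' @examples
#' ckd_stage(c(14, 45, 89.999, 90))
#' @export
ckd_stage <- function(gfr, coarse = FALSE) {
  if (length(gfr) == 0L) stop("empty GFR vector")
  if (anyNA(gfr) || any(gfr <= 0)) stop("GFR must be strictly positive")
  s <- cut(gfr, breaks = c(0, 15, 30, 45, 60, 90, Inf),
           labels = .stage_levels, right = FALSE)
  if (coarse) {
    s <- factor(ifelse(s %in% c("G3a", "G3b"), "G3", as.character(s)),
                levels = c("G5", "G4", "G3", "G2", "G1"), ordered = TRUE)
  } else {
    s <- factor(as.character(s), levels = .stage_levels, ordered = TRUE)
  }
  s
}

# Round half away from zero, as printed clinical tables do (base round()
# rounds half to even).
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p + sign(x) * 0.5) / p
}

#' Net reclassification index from reclassification counts
#'
#' Two variants are returned. The printed-style NRI is the difference of
#' the one-decimal-rounded correct and incorrect percentages (the
#' convention that reproduces published reclassification tables); the exact
#' NRI is 100 (correct - incorrect) / n.
#'
#' @param correct Number of samples where the new equation matches the
#'   mGFR-based stage while the comparator does not.
#' @param incorrect Number of samples where the comparator matches the
#'   mGFR-based stage while the new equation does not.
#' @param n Number of samples in the stratum.
#' @return List with `pct_correct`, `pct_incorrect` (one-decimal-rounded
#'   percentages), `nri_printed_style` and `nri_exact`.
#' @examples
#' nri_from_counts(133, 85, 600)  # printed-style NRI 8.0
#' @export
nri_from_counts <- function(correct, incorrect, n) {
  if (n <= 0) stop("n must be positive")
  if (correct < 0 || incorrect < 0 || correct + incorrect > n) {
    stop("invalid reclassification counts")
  }
  pc <- .round_half_up(100 * correct / n, 1)
  pi <- .round_half_up(100 * incorrect / n, 1)
  list(pct_correct = pc, pct_incorrect = pi,
       nri_printed_style = pc - pi,
       nri_exact = 100 * (correct - incorrect) / n)
}

#' CKD-stage reclassification summary and NRI
#'
#' Stages the measured GFR and both estimates, and counts, overall and per
#' mGFR-based stage stratum, the samples where the two equations disagree
#' on the stage (discordant): "correct" reclassifications are discordant
#' samples where the new equation matches the mGFR stage and the comparator
#' does not; "incorrect" the converse; samples where both miss the mGFR
#' stage while disagreeing with each other are reported separately as
#' `both_wrong_discordant`. The stratification variable is the mGFR-derived
#' stage.
#'
#' @param mgfr Measured GFR vector, > 0.
#' @param egfr_new Estimates of the candidate (new) equation.
#' @param egfr_comparator Estimates of the comparator equation.
#' @param stratify If `TRUE`, report per-stage strata in addition to overall.
#' @return Data frame with one row per stratum: `stratum`, `n`,
#'   `total_discordant`, `correct`, `incorrect`, `both_wrong_discordant`,
#'   `pct_correct`, `pct_incorrect`, `nri_printed_style`, `nri_exact`
#'   (NRI columns are `NA` for empty strata).
#' @export
reclassification_summary <- function(mgfr, egfr_new, egfr_comparator,
                                     stratify = TRUE) {
  n <- length(mgfr)
  if (length(egfr_new) != n || length(egfr_comparator) != n) {
    stop("mgfr, egfr_new and egfr_comparator must have equal length")
  }
  if (n == 0L) stop("empty input")
  s_m <- ckd_stage(mgfr)
  s_n <- ckd_stage(egfr_new)
  s_c <- ckd_stage(egfr_comparator)

  discordant <- s_n != s_c
  correct <- discordant & s_n == s_m
  incorrect <- discordant & s_c == s_m
  both_wrong <- discordant & s_n != s_m & s_c != s_m

  one <- function(sel, label) {
    k <- sum(sel)
    if (k == 0L) {
      return(data.frame(stratum = label, n = 0L, total_discordant = 0L,
                        correct = 0L, incorrect = 0L,
                        both_wrong_discordant = 0L,
                        pct_correct = NA_real_, pct_incorrect = NA_real_,
                        nri_printed_style = NA_real_, nri_exact = NA_real_,
                        stringsAsFactors = FALSE))
    }
    nri <- nri_from_counts(sum(correct[sel]), sum(incorrect[sel]), k)
    data.frame(stratum = label, n = k,
               total_discordant = sum(discordant[sel]),
               correct = sum(correct[sel]), incorrect = sum(incorrect[sel]),
               both_wrong_discordant = sum(both_wrong[sel]),
               pct_correct = nri$pct_correct, pct_incorrect = nri$pct_incorrect,
               nri_printed_style = nri$nri_printed_style,
               nri_exact = nri$nri_exact, stringsAsFactors = FALSE)
  }
  out <- one(rep(TRUE, n), "overall")
  if (stratify) {
    for (lv in .stage_levels) {
      out <- rbind(out, one(s_m == lv, lv))
    }
  }
  rownames(out) <- NULL
  out
}
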