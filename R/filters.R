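#' Build a threshold filter rule
#'
#' A rule keeps candidates whose computed field satisfies
#' `op(field, threshold)`; fields are any scalar component of a
#' `gfr_candidate` (`train_mae`, `train_p30`, `cv_mae_cv`,
#' `heteroscedasticity`, `upper_range_reach`, ...).
#'
#' @param id Short rule identifier used in the audit log.
#' @param field Candidate field name.
#' @param op One of `"<="`, `">="`, `"<"`, `">"`.
#' @param threshold Numeric threshold.
#' @return A rule list usable in [apply_filters()].
#' @export
filter_rule <- function(id, field, op = c("<=", ">=", "<", ">"), threshold) {
  op <- match.arg(op)
  list(id = id, type = "threshold", field = field, op = op,
       threshold = threshold)
}

#' Build a redundancy-pruning rule
#'
#' Within groups of candidates sharing at least `min_shared` features
#' (main-effect or interaction terms), candidates that are dominated on
#' both training MAE (higher) and training P20 (lower) by another group
#' member are removed, keeping the Pareto front.
#'
#' @param id Rule identifier.
#' @param min_shared Minimum number of shared features linking two
#'   candidates into the same group.
#' @return A rule list usable in [apply_filters()].
#' @export
redundancy_rule <- function(id = "redundancy", min_shared = 3) {
  list(id = id, type = "redundancy", min_shared = min_shared)
}

#' Load the default deselection rule pipeline
#'
#' Reads the rule configuration shipped with the package (or a user file of
#' the same YAML layout).
#'
#' @param path Optional path to a YAML rule file.
#' @return List of rules for [apply_filters()].
#' @export
default_filter_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "filter_rules.yaml", package = "gfrtools",
                        mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg$rules, function(r) {
    if (identical(r$type, "redundancy")) {
      redundancy_rule(r$id, r$min_shared)
    } else {
      filter_rule(r$id, r$field, r$op, r$threshold)
    }
  })
}

.candidate_features <- function(cand) {
  f <- cand$formula
  terms <- .term_string(f$mains$parameter, f$mains$transform)
  if (!is.null(f$interaction)) {
    it <- f$interaction
    terms <- c(terms, paste(.term_string(it$parameter[1], it$transform[1]),
                            .term_string(it$parameter[2], it$transform[2]),
                            sep = ":"))
  }
  terms
}

.apply_redundancy <- function(candidates, min_shared) {
  k <- length(candidates)
  if (k < 2L) return(seq_len(k))
  feats <- lapply(candidates, .candidate_features)
  # union-find over candidates linked by >= min_shared shared features
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    if (length(intersect(feats[[i]], feats[[j]])) >= min_shared) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(k), find, 0L)
  keep <- rep(TRUE, k)
  mae <- vapply(candidates, `[[`, 0, "train_mae")
  p20 <- vapply(candidates, `[[`, 0, "train_p20")
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(idx) < 2L) next
    for (i in idx) {
      dominated <- any(vapply(idx, function(j) {
        j != i && mae[j] <= mae[i] && p20[j] >= p20[i] &&
          (mae[j] < mae[i] || p20[j] > p20[i])
      }, TRUE))
      if (dominated) keep[i] <- FALSE
    }
  }
  which(keep)
}

#' Apply an ordered deselection rule pipeline to a candidate set
#'
#' Rules are applied in order; each removes the candidates failing it and
#' the removal is recorded in a per-rule audit log. Adding a rule can never
#' enlarge the survivor set.
#'
#' @param candidates List of fitted `gfr_candidate` objects.
#' @param rules List of rules from [filter_rule()], [redundancy_rule()] or
#'   [default_filter_rules()].
#' @return List with `survivors` (the retained candidates) and `audit`
#'   (data frame with `rule_id`, `type`, `removed`, `remaining`).
#' @export
apply_filters <- function(candidates, rules) {
  audit <- data.frame(rule_id = character(0), type = character(0),
                      removed = integer(0), remaining = integer(0),
                      stringsAsFactors = FALSE)
  for (rule in rules) {
    before <- length(candidates)
    if (identical(rule$type, "redundancy")) {
      keep <- .apply_redundancy(candidates, rule$min_shared)
    } else {
      vals <- vapply(candidates, function(cand) {
        v <- cand[[rule$field]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, 0)
      if (anyNA(vals)) {
        stop("rule '", rule$id, "' references uncomputed field '",
             rule$field, "'", call. = FALSE)
      }
      cmp <- switch(rule$op,
                    "<=" = vals <= rule$threshold,
                    ">=" = vals >= rule$threshold,
                    "<"  = vals < rule$threshold,
                    ">"  = vals > rule$threshold,
                    stop("unknown comparator: ", rule$op))
      keep <- which(cmp)
    }
    candidates <- candidates[keep]
    audit <- rbind(audit, data.frame(
      rule_id = rule$id, type = rule$type,
      removed = before - length(candidates),
      remaining = length(candidates), stringsAsFactors = FALSE))
  }
  list(survivors = candidates, audit = audit)
}
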