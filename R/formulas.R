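#' Feature pool for candidate equation formulas
#'
#' The default pool is the ten serum markers of the equation-development
#' pipeline: nine NMR metabolites plus cystatin C. Each parameter may enter
#' a formula untransformed or natural-log transformed, so a pool of P
#' parameters yields 2P possible features.
#'
#' @param parameters Character vector of unique marker names.
#' @param transforms Allowed transforms (`"raw"`, `"log"`).
#' @return An object of class `gfr_feature_pool`.
#' @export
feature_pool <- function(parameters = c("creatinine", "creatine",
                                        "dimethylamine", "dimethyl_sulfone",
                                        "glycerol", "isoleucine", "leucine",
                                        "myo_inositol", "valine", "cystatin_c"),
                         transforms = c("raw", "log")) {
  if (anyDuplicated(parameters)) stop("parameter names must be unique")
  if (!all(transforms %in% c("raw", "log"))) stop("unknown transform")
  structure(list(parameters = parameters, transforms = transforms),
            class = "gfr_feature_pool")
}

#' Constraint set for formula enumeration
#'
#' The four default constraints of the exhaustive search: (1) two to five
#' features per model, (2) at most one interaction term, (3) an interaction
#' must involve at least one parameter already present as a main effect,
#' (4) no parameter may occur with two different transforms anywhere in the
#' model. Toggles allow sensitivity analyses (e.g. permitting
#' self-interactions, i.e. squares).
#'
#' @param min_features,max_features Total feature count bounds (an
#'   interaction counts as one feature).
#' @param allow_interactions Enumerate formulas with one interaction term.
#' @param allow_self_interactions Permit the product of a feature with
#'   itself (excluded by default; parameters are the unit of identity).
#' @param interaction_requires_main Constraint (3) above.
#' @param responses Response transforms to enumerate (`"raw"`, `"log"` for
#'   mGFR and log mGFR).
#' @return A list of class `gfr_constraints`.
#' @export
formula_constraints <- function(min_features = 2, max_features = 5,
                                allow_interactions = TRUE,
                                allow_self_interactions = FALSE,
                                interaction_requires_main = TRUE,
                                responses = c("raw", "log")) {
  if (min_features < 1 || max_features < min_features) stop("invalid feature bounds")
  structure(list(min_features = min_features, max_features = max_features,
                 allow_interactions = allow_interactions,
                 allow_self_interactions = allow_self_interactions,
                 interaction_requires_main = interaction_requires_main,
                 responses = responses),
            class = "gfr_constraints")
}

.parse_term <- function(term) {
  m <- regmatches(term, regexec("^log\\((.+)\\)$", term))[[1]]
  if (length(m) == 2L) c(parameter = m[2], transform = "log")
  else c(parameter = term, transform = "raw")
}

.term_string <- function(parameter, transform) {
  ifelse(transform == "log", paste0("log(", parameter, ")"), parameter)
}

# fast internal constructor used by the enumerator (no validation)
.new_formula <- function(mains_par, mains_tr, int_par = NULL, int_tr = NULL,
                         response = "log") {
  structure(list(mains = data.frame(parameter = mains_par, transform = mains_tr,
                                    stringsAsFactors = FALSE),
                 interaction = if (is.null(int_par)) NULL else
                   list(parameter = int_par, transform = int_tr),
                 response = response),
            class = "gfr_formula")
}

#' Construct a candidate model formula
#'
#' @param mains Character vector of main-effect terms, e.g.
#'   `c("log(creatinine)", "myo_inositol")`.
#' @param interaction Optional character vector of two terms whose product
#'   forms the interaction feature.
#' @param response `"raw"` (mGFR) or `"log"` (log mGFR).
#' @param constraints Constraint set the formula is validated against.
#' @return An object of class `gfr_formula`.
#' @examples
#' model_formula(c("log(cystatin_c)", "log(creatinine)", "myo_inositol"),
#'               response = "log")
#' @export
model_formula <- function(mains, interaction = NULL,
                          response = c("log", "raw"),
                          constraints = formula_constraints()) {
  response <- match.arg(response)
  mp <- t(vapply(mains, .parse_term, c(parameter = "", transform = "")))
  f <- if (!is.null(interaction)) {
    if (length(interaction) != 2L) stop("interaction must be a pair of terms")
    ip <- t(vapply(interaction, .parse_term, c(parameter = "", transform = "")))
    .new_formula(unname(mp[, 1]), unname(mp[, 2]),
                 unname(ip[, 1]), unname(ip[, 2]), response)
  } else {
    .new_formula(unname(mp[, 1]), unname(mp[, 2]), response = response)
  }
  problems <- validate_formula(f, constraints)
  if (length(problems)) stop("invalid formula: ", paste(problems, collapse = "; "))
  f
}

#' Validate a formula against the enumeration constraints
#'
#' @param formula A `gfr_formula`.
#' @param constraints A `gfr_constraints` object.
#' @return Character vector of violated constraints (empty if valid).
#' @export
validate_formula <- function(formula, constraints = formula_constraints()) {
  problems <- character(0)
  m <- formula$mains
  if (anyDuplicated(m$parameter)) {
    problems <- c(problems, "duplicated parameter among main effects")
  }
  n_feat <- nrow(m) + !is.null(formula$interaction)
  if (n_feat < constraints$min_features || n_feat > constraints$max_features) {
    problems <- c(problems, sprintf("feature count %d outside [%d, %d]",
                                    n_feat, constraints$min_features,
                                    constraints$max_features))
  }
  tr_of <- setNames(m$transform, m$parameter)
  if (!is.null(formula$interaction)) {
    it <- formula$interaction
    if (!constraints$allow_interactions) {
      problems <- c(problems, "interactions disabled")
    }
    if (it$parameter[1] == it$parameter[2] && !constraints$allow_self_interactions) {
      problems <- c(problems, "self-interaction not allowed")
    }
    if (constraints$interaction_requires_main &&
        !any(it$parameter %in% m$parameter)) {
      problems <- c(problems, "interaction has no parameter among main effects")
    }
    for (i in 1:2) {
      p <- it$parameter[i]
      if (p %in% names(tr_of) && tr_of[[p]] != it$transform[i]) {
        problems <- c(problems,
                      paste0("parameter '", p, "' occurs with two transforms"))
      }
    }
    if (it$parameter[1] == it$parameter[2] &&
        it$transform[1] != it$transform[2]) {
      problems <- c(problems, paste0("parameter '", it$parameter[1],
                                     "' occurs with two transforms"))
    }
  }
  if (!formula$response %in% constraints$responses) {
    problems <- c(problems, "response transform not enabled")
  }
  problems
}

#' @export
format.gfr_formula <- function(x, ...) {
  lhs <- if (x$response == "log") "log(mgfr)" else "mgfr"
  terms <- .term_string(x$mains$parameter, x$mains$transform)
  if (!is.null(x$interaction)) {
    it <- x$interaction
    terms <- c(terms, paste(.term_string(it$parameter[1], it$transform[1]),
                            .term_string(it$parameter[2], it$transform[2]),
                            sep = ":"))
  }
  paste(lhs, "~", paste(terms, collapse = " + "))
}

#' @export
print.gfr_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# all transform assignments for k slots
.transform_grid <- function(transforms, k) {
  g <- as.matrix(expand.grid(rep(list(transforms), k),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  g[, rev(seq_len(k)), drop = FALSE]  # first slot varies slowest
}

#' Enumerate all candidate formulas under the constraints
#'
#' Yields every formula satisfying the constraint set exactly once, for
#' every enabled response transform, in a deterministic canonical order
#' (response, main-effect subset, transform assignment, interaction
#' choice). With a `callback`, formulas are streamed one at a time in
#' constant memory and only the count is returned.
#'
#' @param pool A [feature_pool()].
#' @param constraints A [formula_constraints()] set.
#' @param callback Optional `function(formula)` called on each formula.
#' @return List of `gfr_formula` objects, or (invisibly) the count when a
#'   callback is supplied.
#' @examples
#' length(enumerate_formulas(feature_pool(c("a", "b"))))  # 32
#' @export
enumerate_formulas <- function(pool, constraints = formula_constraints(),
                               callback = NULL) {
  params <- pool$parameters
  P <- length(params)
  transforms <- pool$transforms
  streaming <- !is.null(callback)
  out <- if (streaming) NULL else vector("list", 1024L)
  count <- 0L
  emit <- function(f) {
    count <<- count + 1L
    if (streaming) callback(f)
    else {
      if (count > length(out)) length(out) <<- 2L * length(out)
      out[[count]] <<- f
    }
  }

  for (resp in constraints$responses) {
    max_main <- min(constraints$max_features, P)
    lo_main <- max(1L, constraints$min_features -
                     as.integer(constraints$allow_interactions))
    for (m in lo_main:max_main) {
      if (m > P) next
      subsets <- utils::combn(P, m)
      tg <- .transform_grid(transforms, m)
      for (si in seq_len(ncol(subsets))) {
        idx <- subsets[, si]
        mains_par <- params[idx]
        outside <- setdiff(seq_len(P), idx)
        for (ti in seq_len(nrow(tg))) {
          mains_tr <- tg[ti, ]
          if (m >= constraints$min_features && m <= constraints$max_features) {
            emit(.new_formula(mains_par, mains_tr, response = resp))
          }
          if (!constraints$allow_interactions) next
          if (m + 1L < constraints$min_features ||
              m + 1L > constraints$max_features) next
          # (a) both interaction parameters among the mains (transforms forced)
          if (m >= 2L) {
            for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
              emit(.new_formula(mains_par, mains_tr,
                                c(mains_par[i], mains_par[j]),
                                c(mains_tr[i], mains_tr[j]), resp))
            }
          }
          # (b) one parameter in the mains, partner outside (free transform)
          for (i in seq_len(m)) for (o in outside) for (tb in transforms) {
            emit(.new_formula(mains_par, mains_tr,
                              c(mains_par[i], params[o]),
                              c(mains_tr[i], tb), resp))
          }
          # (c) self-interactions of a main effect
          if (constraints$allow_self_interactions) {
            for (i in seq_len(m)) {
              emit(.new_formula(mains_par, mains_tr,
                                c(mains_par[i], mains_par[i]),
                                c(mains_tr[i], mains_tr[i]), resp))
            }
          }
          # (d) interactions fully outside the mains
          if (!constraints$interaction_requires_main && length(outside) > 0L) {
            for (oi in seq_along(outside)) {
              for (ta in transforms) {
                if (constraints$allow_self_interactions) {
                  emit(.new_formula(mains_par, mains_tr,
                                    rep(params[outside[oi]], 2), rep(ta, 2), resp))
                }
                if (oi < length(outside)) {
                  for (oj in (oi + 1L):length(outside)) for (tb in transforms) {
                    emit(.new_formula(mains_par, mains_tr,
                                      c(params[outside[oi]], params[outside[oj]]),
                                      c(ta, tb), resp))
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  if (streaming) return(invisible(count))
  length(out) <- count
  out
}

#' Closed-form count of candidate formulas
#'
#' Counts, without enumeration, the formulas [enumerate_formulas()] yields
#' under the same constraints: per response, sum over main-effect counts k
#' of C(P,k) 2^k main-only models, plus sum over m of C(P,m) 2^m times the
#' number of admissible interaction choices. For the default constraints on
#' the ten-parameter pool this is 487,008.
#'
#' @inheritParams enumerate_formulas
#' @return Integer count.
#' @examples
#' count_formulas(feature_pool(c("a", "b")))  # 32
#' @export
count_formulas <- function(pool, constraints = formula_constraints()) {
  P <- length(pool$parameters)
  Tn <- length(pool$transforms)
  main_only <- 0
  lo <- max(1L, constraints$min_features)
  hi <- min(constraints$max_features, P)
  if (lo <= hi) {
    for (k in lo:hi) main_only <- main_only + choose(P, k) * Tn^k
  }
  with_int <- 0
  if (constraints$allow_interactions) {
    lo_m <- max(1L, constraints$min_features - 1L)
    hi_m <- min(constraints$max_features - 1L, P)
    if (lo_m <= hi_m) {
      for (m in lo_m:hi_m) {
        opts <- choose(m, 2) + Tn * m * (P - m)
        if (constraints$allow_self_interactions) opts <- opts + m
        if (!constraints$interaction_requires_main) {
          opts <- opts + Tn^2 * choose(P - m, 2)
          if (constraints$allow_self_interactions) opts <- opts + Tn * (P - m)
        }
        with_int <- with_int + choose(P, m) * Tn^m * opts
      }
    }
  }
  (main_only + with_int) * length(constraints$responses)
}
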