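#' Engineer a piecewise sex/cutoff model from a fitted candidate
#'
#' Refits the candidate jointly on the natural-log GFR scale with branch
#' structure: the intercept and the coefficient of the pivot marker's term
#' become branch-specific, while all other coefficients are shared across
#' branches (the layout of the final piecewise power-law equation, whose
#' branch rows print identical non-pivot coefficients). Branches are
#' defined by sex (optional) and by the pivot marker against a sex-specific
#' concentration cutoff; a value exactly at the cutoff belongs to the
#' at-or-above branch. A linear age term can be added in the same refit.
#'
#' @param candidate Fitted `gfr_candidate` whose formula contains the pivot
#'   parameter as a main effect.
#' @param cohort Training cohort with markers, sex and measured GFR.
#' @param pivot Parameter receiving branch-specific coefficients (e.g.
#'   `"cystatin_c"`).
#' @param cutoffs Named numeric cutoffs per sex, e.g.
#'   `c(female = 1.02, male = 1.22)`; a single unnamed value is used for
#'   both sexes.
#' @param sex_dependent If `TRUE`, branches are sex x cutoff side (four
#'   branches); otherwise cutoff side only (two).
#' @param add_age Add a shared linear age term to the refit.
#' @return An object of class `gfr_piecewise` with a `branches` table
#'   (multiplicative intercept and pivot exponent per branch, with
#'   standard errors) and a `shared` coefficient table.
#' @export
engineer_piecewise <- function(candidate, cohort, pivot = "cystatin_c",
                               cutoffs = c(female = 1.02, male = 1.22),
                               sex_dependent = TRUE, add_age = FALSE) {
  stopifnot(inherits(candidate, "gfr_candidate"))
  f <- candidate$formula
  ip <- which(f$mains$parameter == pivot)
  if (length(ip) != 1L) {
    stop("pivot '", pivot, "' must appear exactly once among the main effects")
  }
  pivot_tr <- f$mains$transform[ip]
  pivot_col <- .term_column(cohort, pivot, pivot_tr)
  pivot_raw <- .resolve_param(cohort, pivot)
  n <- length(pivot_col)

  if (is.null(names(cutoffs))) {
    if (length(cutoffs) != 1L) stop("unnamed cutoffs must be a single value")
    cutoffs <- c(female = unname(cutoffs), male = unname(cutoffs))
  }
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  female <- .sex_female(cohort)
  cut_row <- ifelse(female, cutoffs[["female"]], cutoffs[["male"]])
  side <- ifelse(pivot_raw >= cut_row, "at_or_above", "below")
  branch <- if (sex_dependent) {
    paste(ifelse(female, "female", "male"), side)
  } else paste("all", side)
  branch_levels <- if (sex_dependent) {
    c("female below", "female at_or_above", "male below", "male at_or_above")
  } else c("all below", "all at_or_above")
  branch <- factor(branch, levels = branch_levels)
  if (any(!branch_levels %in% branch)) {
    # tolerate genuinely empty branches only by erroring clearly
    empty <- setdiff(branch_levels, as.character(unique(branch)))
    stop("branch '", empty[1], "' has no samples")
  }

  # shared design: all candidate terms except the pivot main effect
  shared_mains <- f$mains[-ip, , drop = FALSE]
  shared_terms <- .term_string(shared_mains$parameter, shared_mains$transform)
  shared_cols <- lapply(seq_len(nrow(shared_mains)), function(i) {
    .term_column(cohort, shared_mains$parameter[i], shared_mains$transform[i])
  })
  if (!is.null(f$interaction)) {
    it <- f$interaction
    shared_cols[[length(shared_cols) + 1L]] <-
      .term_column(cohort, it$parameter[1], it$transform[1]) *
      .term_column(cohort, it$parameter[2], it$transform[2])
    shared_terms <- c(shared_terms,
                      paste(.term_string(it$parameter[1], it$transform[1]),
                            .term_string(it$parameter[2], it$transform[2]),
                            sep = ":"))
  }
  if (add_age) {
    shared_cols[[length(shared_cols) + 1L]] <- .get_age(cohort)
    shared_terms <- c(shared_terms, "age")
  }

  n_shared <- length(shared_terms)
  for (b in branch_levels) {
    nb <- sum(branch == b)
    if (nb < n_shared + 2L) {
      stop("branch '", b, "' has only ", nb,
           " samples, fewer than its coefficient count")
    }
  }

  B <- stats::model.matrix(~ 0 + branch)
  colnames(B) <- branch_levels
  X <- cbind(B, B * pivot_col)
  colnames(X) <- c(paste0("intercept:", branch_levels),
                   paste0("pivot:", branch_levels))
  if (n_shared > 0L) {
    S <- do.call(cbind, shared_cols)
    colnames(S) <- shared_terms
    X <- cbind(X, S)
  }
  y <- log(.get_marker(cohort, "mgfr"))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear piecewise design")
  beta <- qr.coef(qrX, y)
  res <- as.vector(y - X %*% beta)
  sigma2 <- sum(res^2) / (n - ncol(X))
  Rinv <- backsolve(qr.R(qrX), diag(ncol(X)))
  se <- setNames(numeric(ncol(X)), colnames(X))
  se[qrX$pivot] <- sqrt(sigma2 * rowSums(Rinv^2))

  branches <- data.frame(
    branch = branch_levels,
    sex = if (sex_dependent) sub(" .*$", "", branch_levels) else "all",
    side = sub("^[^ ]+ ", "", branch_levels),
    cutoff = if (sex_dependent)
      unname(cutoffs[sub(" .*$", "", branch_levels)]) else unname(cutoffs[1]),
    n = as.integer(table(branch)[branch_levels]),
    intercept_log = unname(beta[paste0("intercept:", branch_levels)]),
    intercept = exp(unname(beta[paste0("intercept:", branch_levels)])),
    pivot_exponent = unname(beta[paste0("pivot:", branch_levels)]),
    se_intercept_log = unname(se[paste0("intercept:", branch_levels)]),
    se_pivot_exponent = unname(se[paste0("pivot:", branch_levels)]),
    stringsAsFactors = FALSE)

  shared <- data.frame(term = shared_terms,
                       estimate = unname(beta[shared_terms]),
                       se = unname(se[shared_terms]),
                       stringsAsFactors = FALSE)

  mgfr <- .get_marker(cohort, "mgfr")
  pred <- exp(y - res)
  structure(list(
    pivot = pivot, pivot_transform = pivot_tr, sex_dependent = sex_dependent,
    cutoffs = cutoffs, branches = branches, shared = shared,
    sigma = sqrt(sigma2), n = n,
    fitted_gfr = pred, residuals_response = res, mgfr = mgfr,
    train_mae = mean(abs(pred - mgfr)),
    formula = f, add_age = add_age
  ), class = "gfr_piecewise")
}

#' @export
print.gfr_piecewise <- function(x, ...) {
  cat("Piecewise equation (pivot:", x$pivot, "on log-GFR scale)\n")
  print(x$branches[, c("branch", "cutoff", "n", "intercept", "pivot_exponent")],
        row.names = FALSE)
  if (nrow(x$shared)) {
    cat("Shared coefficients:\n")
    print(x$shared, row.names = FALSE)
  }
  cat(sprintf("n = %d, train MAE = %.2f\n", x$n, x$train_mae))
  invisible(x)
}

#' @export
coef.gfr_piecewise <- function(object, ...) {
  c(setNames(object$branches$intercept_log,
             paste0("intercept:", object$branches$branch)),
    setNames(object$branches$pivot_exponent,
             paste0("pivot:", object$branches$branch)),
    setNames(object$shared$estimate, object$shared$term))
}

#' @export
predict.gfr_piecewise <- function(object, newdata, ...) {
  pivot_col <- .term_column(newdata, object$pivot, object$pivot_transform)
  pivot_raw <- .resolve_param(newdata, object$pivot)
  female <- .sex_female(newdata)
  cut_row <- ifelse(female, object$cutoffs[["female"]], object$cutoffs[["male"]])
  side <- ifelse(pivot_raw >= cut_row, "at_or_above", "below")
  branch <- if (object$sex_dependent) {
    paste(ifelse(female, "female", "male"), side)
  } else paste("all", side)
  bi <- match(branch, object$branches$branch)
  if (anyNA(bi)) stop("sample falls in a branch absent from the fit")
  yhat <- object$branches$intercept_log[bi] +
    object$branches$pivot_exponent[bi] * pivot_col
  for (i in seq_len(nrow(object$shared))) {
    term <- object$shared$term[i]
    col <- if (term == "age") .get_age(newdata) else {
      pt <- .parse_term(sub(":.*$", "", term))
      if (grepl(":", term)) {
        pt2 <- .parse_term(sub("^.*:", "", term))
        .term_column(newdata, pt[["parameter"]], pt[["transform"]]) *
          .term_column(newdata, pt2[["parameter"]], pt2[["transform"]])
      } else {
        .term_column(newdata, pt[["parameter"]], pt[["transform"]])
      }
    }
    yhat <- yhat + object$shared$estimate[i] * col
  }
  exp(yhat)
}

#' @export
residuals.gfr_piecewise <- function(object, type = c("gfr", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals_response
  else object$fitted_gfr - object$mgfr
}

#' @export
fitted.gfr_piecewise <- function(object, ...) object$fitted_gfr

#' @export
simulate.gfr_piecewise <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  mu <- log(object$fitted_gfr)
  out <- replicate(nsim, exp(mu + rnorm(object$n, 0, object$sigma)))
  as.data.frame(out)
}

#' Convert a piecewise fit to an equation coefficient table
#'
#' Expresses a four-branch piecewise fit with pivot `cystatin_c` (log
#' transform) and shared terms drawn from log(creatinine), log(valine),
#' raw myo-inositol and raw age as a coefficient table of the same
#' structure as the shipped published equation, directly usable by
#' [estimate_gfr_nmr()] (and serializable with `yaml::write_yaml()`).
#'
#' @param x A `gfr_piecewise` fit.
#' @param round_digits Round exponents/bases to this many digits and
#'   intercepts to whole numbers, as the published table does; `NULL`
#'   keeps full precision.
#' @return Coefficient list in the [gfr_equation_coefficients()] layout.
#' @export
as_coefficient_table <- function(x, round_digits = NULL) {
  stopifnot(inherits(x, "gfr_piecewise"))
  if (!x$sex_dependent || nrow(x$branches) != 4L) {
    stop("a sex x cutoff fit with four branches is required")
  }
  if (x$pivot != "cystatin_c" || x$pivot_transform != "log") {
    stop("the published table layout requires pivot log(cystatin_c)")
  }
  allowed <- c("log(creatinine)", "log(valine)", "myo_inositol", "age")
  extra <- setdiff(x$shared$term, allowed)
  if (length(extra)) {
    stop("shared terms not representable in the published layout: ",
         paste(extra, collapse = ", "))
  }
  g <- function(term, default = 0) {
    i <- match(term, x$shared$term)
    if (is.na(i)) default else x$shared$estimate[i]
  }
  rd <- function(v, d) if (is.null(round_digits)) v else round(v, d)
  cfg <- list(
    equation = "gfr_nmr",
    version = "refit",
    shared = list(
      creatinine_exponent = rd(g("log(creatinine)"), 4),
      valine_exponent = rd(g("log(valine)"), 4),
      myo_inositol_base = rd(exp(g("myo_inositol")), 4),
      age_base = rd(exp(g("age")), 4)
    ),
    pivot_marker = "cystatin_c",
    branches = lapply(seq_len(4L), function(i) {
      b <- x$branches[i, ]
      list(sex = b$sex, side = b$side, pivot_cutoff = b$cutoff,
           intercept = if (is.null(round_digits)) b$intercept
                       else round(b$intercept),
           pivot_exponent = rd(b$pivot_exponent, 4))
    })
  )
  validate_piecewise_coefficients(cfg)
  cfg
}
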