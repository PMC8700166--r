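# Cohort tables use the canonical column schema of read_cohort(); the
# accessors below also accept bare marker names so that ad-hoc data frames
# (e.g. in simulations) work without renaming.
.marker_aliases <- list(
  age          = c("age_years", "age"),
  sex          = "sex",
  black        = "black",
  creatinine   = c("scr_umol_l", "creatinine"),
  creatinine_mg_dl = "scr_mg_dl",
  cystatin_c   = c("scys_mg_l", "cystatin_c"),
  valine       = c("valine_umol_l", "valine"),
  myo_inositol = c("myo_inositol_umol_l", "myo_inositol"),
  height       = c("height_cm", "height"),
  weight       = c("weight_kg", "weight"),
  mgfr         = c("mgfr_ml_min_173", "mgfr")
)

.find_column <- function(cohort, marker) {
  for (a in .marker_aliases[[marker]]) {
    if (a %in% names(cohort)) return(a)
  }
  NULL
}

.get_marker <- function(cohort, marker, positive = TRUE) {
  col <- .find_column(cohort, marker)
  if (is.null(col)) {
    if (marker == "creatinine") {
      col <- .find_column(cohort, "creatinine_mg_dl")
      if (!is.null(col)) return(convert_creatinine(cohort[[col]], "mg_dl"))
    }
    stop("missing required marker: ", marker, call. = FALSE)
  }
  x <- cohort[[col]]
  if (anyNA(x)) stop("missing required marker: ", marker,
                     " (NA in column '", col, "')", call. = FALSE)
  if (positive && (any(!is.finite(x)) || any(x <= 0))) {
    stop(marker, " must be strictly positive", call. = FALSE)
  }
  x
}

.get_age <- function(cohort) {
  age <- .get_marker(cohort, "age")
  if (any(age < 18)) {
    warning("age below 18: equations were developed on adults", call. = FALSE)
  }
  age
}

.sex_female <- function(cohort) {
  col <- .find_column(cohort, "sex")
  if (is.null(col)) stop("missing required marker: sex", call. = FALSE)
  s <- tolower(as.character(cohort[[col]]))
  female <- s %in% c("f", "female")
  male <- s %in% c("m", "male")
  if (any(!(female | male)) || anyNA(s)) {
    stop("sex must be coded F/M or female/male", call. = FALSE)
  }
  female
}

.is_black <- function(cohort) {
  col <- .find_column(cohort, "black")
  if (is.null(col)) return(rep(FALSE, nrow(cohort)))
  b <- cohort[[col]]
  if (is.logical(b)) b <- as.integer(b)
  ifelse(is.na(b), FALSE, b != 0)
}

#' Estimate GFR with the piecewise metabolite (GFR-NMR) equation
#'
#' Evaluates the four-branch power-law equation combining serum cystatin C,
#' creatinine, valine and myo-inositol with age and sex. The branch is
#' selected by sex and by serum cystatin C against the sex-specific cutoff
#' (1.02 mg/L female, 1.22 mg/L male); a value exactly at the cutoff takes
#' the at-or-above branch. Units: creatinine, valine, myo-inositol in
#' umol/L; cystatin C in mg/L; output in mL/min/1.73 m^2, unrounded.
#'
#' @param cohort A data frame with columns `sex`, `age_years`, `scr_umol_l`,
#'   `scys_mg_l`, `valine_umol_l`, `myo_inositol_umol_l` (bare marker names
#'   are also accepted).
#' @param coefficients Coefficient table, default the shipped published one;
#'   see [gfr_equation_coefficients()] and [as_coefficient_table()].
#' @return Numeric vector of eGFR values.
#' @examples
#' pt <- data.frame(sex = "F", age_years = 50, scr_umol_l = 70,
#'                  scys_mg_l = 0.9, valine_umol_l = 250,
#'                  myo_inositol_umol_l = 30)
#' estimate_gfr_nmr(pt)
#' @export
estimate_gfr_nmr <- function(cohort, coefficients = NULL) {
  if (is.null(coefficients)) coefficients <- gfr_equation_coefficients("gfr_nmr")
  validate_piecewise_coefficients(coefficients)
  female <- .sex_female(cohort)
  age <- .get_age(cohort)
  cys <- .get_marker(cohort, "cystatin_c")
  cre <- .get_marker(cohort, "creatinine")
  val <- .get_marker(cohort, "valine")
  myo <- .get_marker(cohort, "myo_inositol")

  sh <- coefficients$shared
  intercept <- numeric(length(cys))
  pivot_exp <- numeric(length(cys))
  for (b in coefficients$branches) {
    in_sex <- if (b$sex == "female") female else !female
    sel <- if (b$side == "below") in_sex & cys < b$pivot_cutoff
           else in_sex & cys >= b$pivot_cutoff
    intercept[sel] <- b$intercept
    pivot_exp[sel] <- b$pivot_exponent
  }
  intercept * cys^pivot_exp * cre^sh$creatinine_exponent *
    val^sh$valine_exponent * sh$myo_inositol_base^myo * sh$age_base^age
}

#' Estimate GFR with a CKD-EPI equation
#'
#' Evaluates the published min/max spline forms: the 2009 creatinine
#' equation, the 2012 cystatin C equation, or the 2012 combined
#' creatinine-cystatin C equation. Creatinine is converted internally to
#' mg/dL (factor 88.42). The race coefficient is applied exactly as
#' published and defaults to non-black when the `black` column is absent.
#'
#' @inheritParams estimate_gfr_nmr
#' @param variant `"cr2009"`, `"cys2012"` or `"crcys2012"`.
#' @return Numeric vector of eGFR values in mL/min/1.73 m^2, unrounded.
#' @export
estimate_ckd_epi <- function(cohort, variant = c("cr2009", "cys2012", "crcys2012")) {
  variant <- match.arg(variant)
  female <- .sex_female(cohort)
  age <- .get_age(cohort)
  black <- .is_black(cohort)
  sexf <- function(x) ifelse(female, x$female, x$male)

  if (variant == "cr2009") {
    cfg <- gfr_equation_coefficients("ckd_epi_2009")
    scr <- .get_marker(cohort, "creatinine") / 88.42
    r <- scr / sexf(cfg$kappa)
    cfg$intercept * pmin(r, 1)^sexf(cfg$alpha) * pmax(r, 1)^cfg$max_exponent *
      cfg$age_base^age * ifelse(female, cfg$female_factor, 1) *
      ifelse(black, cfg$black_factor, 1)
  } else if (variant == "cys2012") {
    cfg <- gfr_equation_coefficients("ckd_epi_cys")
    scys <- .get_marker(cohort, "cystatin_c")
    r <- scys / cfg$cystatin_knot
    cfg$intercept * pmin(r, 1)^cfg$min_exponent * pmax(r, 1)^cfg$max_exponent *
      cfg$age_base^age * ifelse(female, cfg$female_factor, 1)
  } else {
    cfg <- gfr_equation_coefficients("ckd_epi_2012")
    scr <- .get_marker(cohort, "creatinine") / 88.42
    scys <- .get_marker(cohort, "cystatin_c")
    rcr <- scr / sexf(cfg$kappa)
    rcys <- scys / cfg$cystatin_knot
    cfg$intercept * pmin(rcr, 1)^sexf(cfg$alpha) *
      pmax(rcr, 1)^cfg$creatinine_max_exponent *
      pmin(rcys, 1)^cfg$cystatin_min_exponent *
      pmax(rcys, 1)^cfg$cystatin_max_exponent *
      cfg$age_base^age * ifelse(female, cfg$female_factor, 1) *
      ifelse(black, cfg$black_factor, 1)
  }
}

#' Estimate GFR with the EKFC creatinine equation
#'
#' eGFR = 107.3 x (Scr/Q)^-alpha, times 0.990^(age - 40) when age > 40,
#' where alpha is 0.322 below the rescaling point (Scr/Q < 1) and 1.132 at
#' or above it. The sex-specific rescaling constant Q is 0.70 mg/dL
#' (female) and 0.90 mg/dL (male) from age 25 up; below 25 the published
#' age polynomial for ln Q is used.
#'
#' @inheritParams estimate_gfr_nmr
#' @return Numeric vector of eGFR values in mL/min/1.73 m^2, unrounded.
#' @export
estimate_ekfc <- function(cohort) {
  cfg <- gfr_equation_coefficients("ekfc")
  female <- .sex_female(cohort)
  age <- .get_age(cohort)
  scr <- .get_marker(cohort, "creatinine") / 88.42

  q <- ifelse(female, cfg$adult_q_mg_dl$female, cfg$adult_q_mg_dl$male)
  young <- age < cfg$adult_age
  if (any(young)) {
    qy <- function(coefs, a) {
      exp(coefs[1] + coefs[2] * a + coefs[3] * log(a) +
            coefs[4] * a^2 + coefs[5] * a^3) / 88.42
    }
    pf <- unlist(cfg$young_q_log_umol_poly$female)
    pm <- unlist(cfg$young_q_log_umol_poly$male)
    q[young] <- ifelse(female[young], qy(pf, age[young]), qy(pm, age[young]))
  }
  r <- scr / q
  alpha <- ifelse(r < 1, cfg$alpha_low, cfg$alpha_high)
  agef <- ifelse(age > cfg$age_knot, cfg$age_base^(age - cfg$age_knot), 1)
  cfg$intercept * r^(-alpha) * agef
}

.equation_registry <- list(
  gfr_nmr      = function(cohort) estimate_gfr_nmr(cohort),
  ckd_epi_2009 = function(cohort) estimate_ckd_epi(cohort, "cr2009"),
  ckd_epi_cys  = function(cohort) estimate_ckd_epi(cohort, "cys2012"),
  ckd_epi_2012 = function(cohort) estimate_ckd_epi(cohort, "crcys2012"),
  ekfc         = function(cohort) estimate_ekfc(cohort)
)

#' Names of the built-in eGFR equations
#' @return Character vector of equation identifiers.
#' @export
gfr_equations <- function() names(.equation_registry)

#' Add eGFR columns for one or more equations to a cohort
#'
#' @inheritParams estimate_gfr_nmr
#' @param equations Character vector of equation ids, see [gfr_equations()].
#' @return The cohort with one `egfr_<equation>_ml_min_173` column appended
#'   per requested equation.
#' @export
estimate_gfr <- function(cohort, equations = gfr_equations()) {
  bad <- setdiff(equations, names(.equation_registry))
  if (length(bad)) stop("unknown equation(s): ", paste(bad, collapse = ", "))
  for (eq in equations) {
    cohort[[paste0("egfr_", eq, "_ml_min_173")]] <- .equation_registry[[eq]](cohort)
  }
  cohort
}
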