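.coef_cache <- new.env(parent = emptyenv())

#' Equation coefficient tables
#'
#' All published coefficients are shipped as versioned, human-readable YAML
#' documents under `inst/extdata/equations/` (one document per equation) so
#' that they are data, not code. This accessor loads and validates them.
#'
#' @param equation One of `"gfr_nmr"`, `"ckd_epi_2009"`, `"ckd_epi_cys"`,
#'   `"ckd_epi_2012"`, `"ekfc"`.
#' @param path Optional path to an alternative YAML document (e.g. a refitted
#'   coefficient set written by [as_coefficient_table()]).
#' @return A named list mirroring the YAML structure.
#' @examples
#' cfg <- gfr_equation_coefficients("gfr_nmr")
#' cfg$shared$creatinine_exponent
#' @export
gfr_equation_coefficients <- function(equation = c("gfr_nmr", "ckd_epi_2009",
                                                   "ckd_epi_cys", "ckd_epi_2012",
                                                   "ekfc"),
                                      path = NULL) {
  if (is.null(path)) {
    equation <- match.arg(equation)
    if (!is.null(.coef_cache[[equation]])) return(.coef_cache[[equation]])
    path <- system.file("extdata", "equations", paste0(equation, ".yaml"),
                        package = "gfrtools", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    if (identical(equation, "gfr_nmr")) validate_piecewise_coefficients(cfg)
    .coef_cache[[equation]] <- cfg
    return(cfg)
  }
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$equation, "gfr_nmr")) validate_piecewise_coefficients(cfg)
  cfg
}

#' Validate a piecewise power-law coefficient table
#'
#' Checks the structural invariants of the GFR-NMR style coefficient table:
#' two sexes times two cutoff sides (four branches), exponents shared across
#' branches, multiplicative bases in (0, 1], positive cutoffs and intercepts.
#'
#' @param cfg A coefficient list as returned by [gfr_equation_coefficients()].
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_piecewise_coefficients <- function(cfg) {
  br <- cfg$branches
  if (length(br) != 4L) stop("piecewise table must have exactly 4 branches")
  key <- vapply(br, function(b) paste(b$sex, b$side), "")
  need <- c("female below", "female at_or_above", "male below", "male at_or_above")
  if (!setequal(key, need)) {
    stop("branches must cover 2 sexes x 2 cutoff sides, got: ",
         paste(key, collapse = ", "))
  }
  for (b in br) {
    if (!is.numeric(b$pivot_cutoff) || b$pivot_cutoff <= 0) {
      stop("pivot cutoffs must be positive")
    }
    if (!is.numeric(b$intercept) || b$intercept <= 0) {
      stop("branch intercepts must be positive")
    }
  }
  sexes <- vapply(br, `[[`, "", "sex")
  for (s in c("female", "male")) {
    cuts <- unique(vapply(br[sexes == s], `[[`, 0, "pivot_cutoff"))
    if (length(cuts) != 1L) stop("the two ", s, " branches must share a cutoff")
  }
  sh <- cfg$shared
  for (f in c("creatinine_exponent", "valine_exponent",
              "myo_inositol_base", "age_base")) {
    if (!is.numeric(sh[[f]])) stop("missing shared coefficient: ", f)
  }
  if (sh$myo_inositol_base <= 0 || sh$myo_inositol_base > 1 ||
      sh$age_base <= 0 || sh$age_base > 1) {
    stop("multiplicative bases must lie in (0, 1]")
  }
  invisible(cfg)
}
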