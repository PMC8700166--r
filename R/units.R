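#' Convert serum creatinine to micromoles per litre
#'
#' The package's canonical creatinine unit is umol/L; benchmark equations
#' published in mg/dL convert internally using the molar-mass factor 88.42.
#'
#' @param value Numeric vector of creatinine concentrations, strictly
#'   positive.
#' @param from_unit Unit of `value`: `"mg_dl"` or `"umol_l"`.
#' @return Numeric vector in umol/L.
#' @examples
#' convert_creatinine(1.0, "mg_dl")   # 88.42
#' convert_creatinine(88.42, "umol_l")
#' @export
convert_creatinine <- function(value, from_unit = c("umol_l", "mg_dl")) {
  from_unit <- match.arg(from_unit)
  if (length(value) == 0L) stop("no creatinine values supplied")
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("creatinine must be strictly positive and finite")
  }
  if (from_unit == "mg_dl") value * 88.42 else value
}

#' Dubois body surface area
#'
#' BSA (m^2) = 0.007184 x height^0.725 x weight^0.425, with height in cm and
#' weight in kg.
#'
#' @param height_cm Height in centimetres, > 0.
#' @param weight_kg Weight in kilograms, > 0.
#' @return Body surface area in m^2.
#' @examples
#' dubois_bsa(170, 70)
#' @export
dubois_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height must be strictly positive")
  }
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight must be strictly positive")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Normalize a raw clearance to 1.73 m^2 body surface area
#'
#' @param raw_clearance Clearance in mL/min.
#' @param bsa Body surface area in m^2, > 0 (see [dubois_bsa()]).
#' @return Clearance in mL/min/1.73 m^2.
#' @examples
#' normalize_clearance(100, dubois_bsa(170, 70))
#' @export
normalize_clearance <- function(raw_clearance, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("body surface area must be strictly positive")
  }
  raw_clearance * 1.73 / bsa
}
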