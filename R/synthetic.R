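#' Default marker-link coefficients for the cohort generator
#'
#' Each serum marker is generated as
#' `exp(intercept + mgfr_log_slope * ln(mGFR) + sex_shift * male + noise)`,
#' a lognormal link guaranteeing strict positivity. Slopes are signed so
#' that creatinine, cystatin C and myo-inositol decrease with mGFR and
#' valine increases. The coefficients are synthetic calibration choices
#' (not estimated from any study data), set so that typical healthy values
#' appear at mGFR around 90: creatinine about 80 umol/L (male), cystatin C
#' about 0.9 mg/L, myo-inositol about 30 umol/L, valine about 240 umol/L.
#'
#' @return Named list of per-marker link coefficient lists.
#' @export
default_marker_links <- function() {
  list(
    creatinine = list(intercept = 8.06, mgfr_log_slope = -0.85,
                      sex_shift = 0.15, noise_sd = 0.15),
    cystatin_c = list(intercept = 2.99, mgfr_log_slope = -0.70,
                      sex_shift = 0.05, noise_sd = 0.12),
    myo_inositol = list(intercept = 5.88, mgfr_log_slope = -0.55,
                        sex_shift = 0.00, noise_sd = 0.25),
    valine = list(intercept = 4.59, mgfr_log_slope = 0.18,
                  sex_shift = 0.08, noise_sd = 0.15)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginals of the study population the equations
#' target: mGFR 67 +/- 28 (range 3-183) mL/min/1.73 m^2, age 56 +/- 14
#' (18-88) years, 55% male, BMI 30 +/- 6 kg/m^2.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param mgfr_mean,mgfr_sd,mgfr_range Truncated-normal mGFR parameters.
#' @param age_mean,age_sd,age_range Truncated-normal age parameters.
#' @param male_fraction Probability of male sex.
#' @param bmi_mean,bmi_sd,bmi_range Truncated-normal BMI parameters.
#' @param height_mean,height_sd,height_range Truncated-normal height (cm).
#' @param marker_links Per-marker link coefficients, see
#'   [default_marker_links()].
#' @param max_resample Cap on rejection-sampling rounds for truncation.
#' @return A validated list of class `gfr_cohort_config`.
#' @export
cohort_config <- function(n = 600, seed = 1,
                          mgfr_mean = 67, mgfr_sd = 28, mgfr_range = c(3, 183),
                          age_mean = 56, age_sd = 14, age_range = c(18, 88),
                          male_fraction = 0.55,
                          bmi_mean = 30, bmi_sd = 6, bmi_range = c(16, 58),
                          height_mean = 170, height_sd = 10,
                          height_range = c(140, 200),
                          marker_links = default_marker_links(),
                          max_resample = 1000) {
  cfg <- list(n = n, seed = seed, mgfr_mean = mgfr_mean, mgfr_sd = mgfr_sd,
              mgfr_range = mgfr_range, age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, male_fraction = male_fraction,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
              height_mean = height_mean, height_sd = height_sd,
              height_range = height_range, marker_links = marker_links,
              max_resample = max_resample)
  if (n < 1) stop("n must be at least 1")
  for (f in c("mgfr_sd", "age_sd", "bmi_sd", "height_sd")) {
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  }
  for (f in c("mgfr_range", "age_range", "bmi_range", "height_range")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] >= r[2]) stop(f, " must be an increasing pair")
  }
  if (cfg$mgfr_range[1] <= 0) stop("mgfr_range must be positive")
  if (male_fraction < 0 || male_fraction > 1) stop("male_fraction in [0,1]")
  for (m in c("creatinine", "cystatin_c", "myo_inositol")) {
    if (marker_links[[m]]$mgfr_log_slope >= 0) {
      stop(m, " link slope must be negative (marker rises as GFR falls)")
    }
  }
  if (marker_links$valine$mgfr_log_slope <= 0) {
    stop("valine link slope must be positive")
  }
  for (m in names(marker_links)) {
    if (marker_links[[m]]$noise_sd <= 0) stop(m, " noise_sd must be positive")
  }
  structure(cfg, class = "gfr_cohort_config")
}

.rtruncnorm <- function(n, mean, sd, range, max_resample) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(max_resample)) {
    bad <- x < range[1] | x > range[2]
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("truncation rejection-sampling cap exceeded")
}

#' Generate a synthetic patient cohort
#'
#' Draws demographics and anthropometrics from truncated normals, sex from
#' a Bernoulli, and serum markers from lognormal links to the latent
#' measured GFR (see [default_marker_links()]). Liver-disease and clinical
#' indication labels are inert categorical columns carried for
#' stratification only. Output uses the canonical cohort schema of
#' [read_cohort()]. Fully deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `age_years`, `sex`, `black`,
#'   `height_cm`, `weight_kg`, `scr_umol_l`, `scys_mg_l`, `valine_umol_l`,
#'   `myo_inositol_umol_l`, `mgfr_ml_min_173`, `tracer`, `liver_disease`,
#'   `indication`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 7))
#' summary(cohort$mgfr_ml_min_173)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "gfr_cohort_config")) {
    stop("config must be built with cohort_config()")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n
  mgfr <- .rtruncnorm(n, config$mgfr_mean, config$mgfr_sd, config$mgfr_range,
                      config$max_resample)
  age <- .rtruncnorm(n, config$age_mean, config$age_sd, config$age_range,
                     config$max_resample)
  male <- rbinom(n, 1, config$male_fraction)
  height <- .rtruncnorm(n, config$height_mean, config$height_sd,
                        config$height_range, config$max_resample)
  bmi <- .rtruncnorm(n, config$bmi_mean, config$bmi_sd, config$bmi_range,
                     config$max_resample)
  weight <- bmi * (height / 100)^2
  marker <- function(link) {
    exp(link$intercept + link$mgfr_log_slope * log(mgfr) +
          link$sex_shift * male + rnorm(n, 0, link$noise_sd))
  }
  ml <- config$marker_links
  data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age_years = age,
    sex = ifelse(male == 1, "M", "F"),
    black = 0L,
    height_cm = height,
    weight_kg = weight,
    scr_umol_l = marker(ml$creatinine),
    scys_mg_l = marker(ml$cystatin_c),
    valine_umol_l = marker(ml$valine),
    myo_inositol_umol_l = marker(ml$myo_inositol),
    mgfr_ml_min_173 = mgfr,
    tracer = "iothalamate",
    liver_disease = rbinom(n, 1, 0.15),
    indication = sample(c("ckd", "donor", "transplant", "other"), n,
                        replace = TRUE, prob = c(0.45, 0.15, 0.2, 0.2)),
    stringsAsFactors = FALSE
  )
}

#' Replace measured GFR by values simulated from an equation
#'
#' Sets `mgfr = equation(markers) * exp(noise)` with lognormal noise of
#' standard deviation `sigma_log`, so that refitting the equation's
#' log-scale structure on the returned cohort should recover its
#' coefficients. Used for parameter-recovery simulations.
#'
#' @param cohort Cohort with the markers required by the equation.
#' @param coefficients Piecewise coefficient table (default: the shipped
#'   published table).
#' @param sigma_log Standard deviation of the log-scale noise.
#' @param seed Integer seed.
#' @return The cohort with `mgfr_ml_min_173` overwritten.
#' @export
simulate_mgfr <- function(cohort, coefficients = NULL, sigma_log = 0.1,
                          seed = 1) {
  mu <- estimate_gfr_nmr(cohort, coefficients)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  cohort$mgfr_ml_min_173 <- mu * exp(rnorm(length(mu), 0, sigma_log))
  cohort
}

#' Stratified partition of a cohort into three sets
#'
#' Within each stratum cell (the cross-classification of the given
#' columns), rows are shuffled with the seed and allocated to the three
#' sets in the given proportions using largest-remainder rounding, so
#' per-cell proportions deviate from the targets by at most one sample.
#' The three sets are pairwise disjoint and their union is the input.
#'
#' @param cohort Cohort data frame.
#' @param fractions Numeric triple (development, internal, external),
#'   non-negative, summing to 1.
#' @param strata Character vector of cohort column names to stratify on.
#' @param seed Integer seed for the within-cell shuffle.
#' @return Named list `development`, `internal`, `external`.
#' @export
stratified_partition <- function(cohort, fractions = c(0.44, 0.24, 0.32),
                                 strata = "sex", seed = 1) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three non-negative values summing to 1")
  }
  missing_cols <- setdiff(strata, names(cohort))
  if (length(missing_cols)) {
    stop("unknown stratum column(s): ", paste(missing_cols, collapse = ", "))
  }
  empty <- cohort[0, , drop = FALSE]
  out <- list(development = empty, internal = empty, external = empty)
  if (nrow(cohort) == 0L) return(out)
  cell <- if (length(strata)) {
    interaction(cohort[, strata, drop = FALSE], drop = TRUE)
  } else factor(rep(1L, nrow(cohort)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  assign_set <- integer(nrow(cohort))
  for (lv in levels(cell)) {
    idx <- which(cell == lv)
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    target <- fractions * k
    base <- floor(target)
    rem <- k - sum(base)
    if (rem > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    sets <- rep(1:3, times = base)
    assign_set[idx] <- sets
  }
  out$development <- cohort[assign_set == 1L, , drop = FALSE]
  out$internal <- cohort[assign_set == 2L, , drop = FALSE]
  out$external <- cohort[assign_set == 3L, , drop = FALSE]
  out
}
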