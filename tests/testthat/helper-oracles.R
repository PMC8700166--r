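# Independent, deliberately naive scalar transcriptions of the published
# equations, used as oracles against the vectorized implementations.

oracle_gfr_nmr <- function(sex, age, cys, cre, val, myo) {
  shared <- cre^-0.3798 * val^0.1628 * 0.9979^myo * 0.9963^age
  if (sex == "F") {
    if (cys < 1.02) 238 * cys^-0.4114 * shared else 239 * cys^-0.6443 * shared
  } else {
    if (cys < 1.22) 266 * cys^-0.5867 * shared else 269 * cys^-0.6419 * shared
  }
}

oracle_ckd_epi_2009 <- function(sex, age, scr_mg_dl, black) {
  kappa <- if (sex == "F") 0.7 else 0.9
  alpha <- if (sex == "F") -0.329 else -0.411
  out <- 141 * min(scr_mg_dl / kappa, 1)^alpha *
    max(scr_mg_dl / kappa, 1)^-1.209 * 0.993^age
  if (sex == "F") out <- out * 1.018
  if (black) out <- out * 1.159
  out
}

oracle_ckd_epi_cys <- function(sex, age, scys) {
  out <- 133 * min(scys / 0.8, 1)^-0.499 * max(scys / 0.8, 1)^-1.328 * 0.996^age
  if (sex == "F") out <- out * 0.932
  out
}

oracle_ckd_epi_2012 <- function(sex, age, scr_mg_dl, scys, black) {
  kappa <- if (sex == "F") 0.7 else 0.9
  alpha <- if (sex == "F") -0.248 else -0.207
  out <- 135 * min(scr_mg_dl / kappa, 1)^alpha *
    max(scr_mg_dl / kappa, 1)^-0.601 *
    min(scys / 0.8, 1)^-0.375 * max(scys / 0.8, 1)^-0.711 * 0.995^age
  if (sex == "F") out <- out * 0.969
  if (black) out <- out * 1.08
  out
}

oracle_ekfc <- function(sex, age, scr_mg_dl) {
  if (age < 25) {
    q_poly <- if (sex == "F") c(3.080, 0.177, -0.223, -0.00596, 0.0000686)
              else c(3.200, 0.259, -0.543, -0.00763, 0.0000790)
    q <- exp(q_poly[1] + q_poly[2] * age + q_poly[3] * log(age) +
               q_poly[4] * age^2 + q_poly[5] * age^3) / 88.42
  } else {
    q <- if (sex == "F") 0.70 else 0.90
  }
  r <- scr_mg_dl / q
  alpha <- if (r < 1) 0.322 else 1.132
  out <- 107.3 * r^-alpha
  if (age > 40) out <- out * 0.990^(age - 40)
  out
}

# Random valid patient samples spanning the physiological range.
random_samples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_years = runif(n, 18, 88),
    black = sample(0:1, n, replace = TRUE, prob = c(0.9, 0.1)),
    scr_umol_l = runif(n, 40, 900),
    scys_mg_l = runif(n, 0.4, 6),
    valine_umol_l = runif(n, 80, 400),
    myo_inositol_umol_l = runif(n, 10, 200),
    stringsAsFactors = FALSE
  )
}

# Naive brute-force count of admissible formulas: loops over every subset
# of the 2P transformed features for the main effects and every possible
# interaction pair, validating the four constraints literally.
naive_formula_count <- function(P, cons = formula_constraints()) {
  params <- paste0("p", seq_len(P))
  feats <- expand.grid(par = params, tr = c("raw", "log"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nf <- nrow(feats)
  valid_main <- function(idx) !anyDuplicated(feats$par[idx])
  count <- 0L
  max_main <- min(cons$max_features, nf)
  for (k in seq_len(max_main)) {
    sets <- utils::combn(nf, k)
    for (ci in seq_len(ncol(sets))) {
      idx <- sets[, ci]
      if (!valid_main(idx)) next
      if (k >= cons$min_features && k <= cons$max_features) count <- count + 1L
      if (!cons$allow_interactions) next
      if (k + 1L < cons$min_features || k + 1L > cons$max_features) next
      for (i in seq_len(nf)) for (j in i:nf) {
        same_par <- feats$par[i] == feats$par[j]
        if (i == j) {
          if (!cons$allow_self_interactions) next
        } else if (same_par) next  # same parameter, two transforms
        if (cons$interaction_requires_main &&
            !any(feats$par[c(i, j)] %in% feats$par[idx])) next
        # a parameter may not appear with a different transform in the mains
        clash <- FALSE
        for (q in unique(c(i, j))) {
          hit <- which(feats$par[idx] == feats$par[q])
          if (length(hit) && idx[hit] != q) clash <- TRUE
        }
        if (clash) next
        count <- count + 1L
      }
    }
  }
  count * length(cons$responses)
}

# Canonical string for duplicate detection among enumerated formulas.
formula_key <- function(f) {
  mains <- sort(paste(f$mains$parameter, f$mains$transform))
  it <- if (is.null(f$interaction)) "" else {
    paste(sort(paste(f$interaction$parameter, f$interaction$transform)),
          collapse = "*")
  }
  paste(f$response, paste(mains, collapse = "+"), it, sep = "|")
}

# Small noiseless cohort generated from a known log-linear model; used for
# exact-recovery fitting tests.
noiseless_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  d <- data.frame(
    a = exp(rnorm(n, 1, 0.4)),
    b = exp(rnorm(n, 2, 0.3)),
    c = runif(n, 5, 50)
  )
  d$mgfr <- exp(4 - 0.5 * log(d$a) + 0.3 * log(d$b) - 0.01 * d$c)
  d
}
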