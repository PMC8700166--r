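patient <- function(sex = "F", age = 50, cys = 0.9, cre = 70, val = 250,
                    myo = 30, black = 0) {
  data.frame(sex = sex, age_years = age, scys_mg_l = cys, scr_umol_l = cre,
             valine_umol_l = val, myo_inositol_umol_l = myo, black = black,
             stringsAsFactors = FALSE)
}

test_that("piecewise metabolite equation reproduces worked values", {
  expect_equal(estimate_gfr_nmr(patient("F", 50, 0.90, 70, 250, 30)),
               94.87, tolerance = 1e-3)
  expect_equal(estimate_gfr_nmr(patient("M", 60, 2.0, 300, 180, 80)),
               31.13, tolerance = 1e-3)
})

test_that("cystatin C exactly at the cutoff takes the at-or-above branch", {
  at_cut <- estimate_gfr_nmr(patient("F", 50, cys = 1.02))
  manual <- 239 * 1.02^-0.6443 * 70^-0.3798 * 250^0.1628 * 0.9979^30 * 0.9963^50
  expect_equal(at_cut, manual)
  m_cut <- estimate_gfr_nmr(patient("M", 50, cys = 1.22))
  m_manual <- 269 * 1.22^-0.6419 * 70^-0.3798 * 250^0.1628 * 0.9979^30 * 0.9963^50
  expect_equal(m_cut, m_manual)
})

test_that("branch values agree closely at the cutoffs", {
  cfg <- gfr_equation_coefficients("gfr_nmr")
  for (sex in c("female", "male")) {
    branches <- Filter(function(b) b$sex == sex, cfg$branches)
    cut <- branches[[1]]$pivot_cutoff
    vals <- vapply(branches, function(b) {
      b$intercept * cut^b$pivot_exponent
    }, 0)
    expect_lt(abs(vals[1] - vals[2]) / vals[2], 0.005)
  }
})

test_that("CKD-EPI variants reproduce worked values and collapse at knots", {
  f55 <- data.frame(sex = "F", age_years = 55, scr_mg_dl = 0.7)
  expect_equal(estimate_ckd_epi(f55, "cr2009"), 141 * 1.018 * 0.993^55)
  expect_equal(estimate_ckd_epi(f55, "cr2009"), 97.54, tolerance = 1e-3)
  f60 <- data.frame(sex = "F", age_years = 60, scys_mg_l = 0.8)
  expect_equal(estimate_ckd_epi(f60, "cys2012"), 133 * 0.932 * 0.996^60)
  m40 <- data.frame(sex = "M", age_years = 40, scr_mg_dl = 0.9, scys_mg_l = 0.8)
  expect_equal(estimate_ckd_epi(m40, "crcys2012"), 135 * 0.995^40)
  expect_equal(estimate_ckd_epi(m40, "crcys2012"), 110.47, tolerance = 1e-3)
})

test_that("EKFC reproduces worked values on both slope branches", {
  expect_equal(estimate_ekfc(data.frame(sex = "M", age_years = 40,
                                        scr_mg_dl = 0.9)), 107.3)
  expect_equal(estimate_ekfc(data.frame(sex = "F", age_years = 60,
                                        scr_mg_dl = 1.4)),
               107.3 * 2^-1.132 * 0.990^20)
  expect_equal(estimate_ekfc(data.frame(sex = "F", age_years = 30,
                                        scr_mg_dl = 0.56)),
               107.3 * 0.8^-0.322)
})

test_that("all five equations match naive scalar transcriptions", {
  samples <- random_samples(300, seed = 2024)
  got <- estimate_gfr(samples)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    expected <- c(
      gfr_nmr = oracle_gfr_nmr(s$sex, s$age_years, s$scys_mg_l, s$scr_umol_l,
                               s$valine_umol_l, s$myo_inositol_umol_l),
      ckd_epi_2009 = oracle_ckd_epi_2009(s$sex, s$age_years,
                                         s$scr_umol_l / 88.42, s$black == 1),
      ckd_epi_cys = oracle_ckd_epi_cys(s$sex, s$age_years, s$scys_mg_l),
      ckd_epi_2012 = oracle_ckd_epi_2012(s$sex, s$age_years,
                                         s$scr_umol_l / 88.42, s$scys_mg_l,
                                         s$black == 1),
      ekfc = oracle_ekfc(s$sex, s$age_years, s$scr_umol_l / 88.42)
    )
    for (eq in names(expected)) {
      expect_equal(got[[paste0("egfr_", eq, "_ml_min_173")]][i],
                   unname(expected[eq]), tolerance = 1e-9)
    }
  }
})

test_that("metabolite equation has the published sign structure", {
  base <- patient("M", 60, 1.5, 120, 200, 60)
  ref <- estimate_gfr_nmr(base)
  bump <- function(col, delta) {
    p <- base; p[[col]] <- p[[col]] + delta; estimate_gfr_nmr(p)
  }
  expect_lt(bump("scys_mg_l", 0.2), ref)
  expect_lt(bump("scr_umol_l", 20), ref)
  expect_lt(bump("myo_inositol_umol_l", 10), ref)
  expect_lt(bump("age_years", 5), ref)
  expect_gt(bump("valine_umol_l", 30), ref)
})

test_that("equations return positive values and validate their inputs", {
  samples <- random_samples(50, seed = 9)
  est <- estimate_gfr(samples)
  for (eq in gfr_equations()) {
    expect_true(all(est[[paste0("egfr_", eq, "_ml_min_173")]] > 0))
  }
  no_cys <- patient(); no_cys$scys_mg_l <- NULL
  expect_error(estimate_gfr_nmr(no_cys), "cystatin_c")
  expect_error(estimate_ckd_epi(data.frame(sex = "F", age_years = 50),
                                "cys2012"), "cystatin_c")
  expect_error(estimate_ekfc(data.frame(sex = "F", age_years = 50)),
               "creatinine")
  neg <- patient(); neg$scr_umol_l <- -1
  expect_error(estimate_gfr_nmr(neg), "positive")
  young <- patient(age = 12)
  expect_warning(estimate_gfr_nmr(young), "adults")
})
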