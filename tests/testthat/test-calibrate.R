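test_that("NIF is the plain isotopomer ratio and requires the SIL-IS", {
  expect_equal(compute_nif(0, 5), 0)
  expect_equal(compute_nif(3, 3), 1)
  expect_error(compute_nif(1, 0), "SIL-IS missing")
  # suppression cancels: noiseless signals at a12/a13 = 7 under heavy load
  m <- instrument_model(nucleosides = "Am", k_sat = 0.5)
  es <- expected_signals(m, 7, 1, "Am")
  expect_equal(compute_nif(es$ms12, es$ms13), 7, tolerance = 1e-12)
})

test_that("linear-range search recovers a perfect line and rejects garbage", {
  x <- 10^seq(-3, 2, by = 0.5)
  mod <- fit_linear_range(x, 250 * x, nucleoside = "Am", channel = "MS12")
  expect_equal(mod$linear_lo, min(x))
  expect_equal(mod$linear_hi, max(x))
  expect_equal(mod$slope, 250, tolerance = 1e-9)
  expect_equal(mod$r2, 1, tolerance = 1e-9)
  expect_equal(mod$decades, 5)
  # blanks are ignored
  mod_b <- fit_linear_range(c(0, x), c(17, 250 * x))
  expect_equal(mod_b$decades, 5)
  # replicates aggregated by median
  mod_r <- fit_linear_range(rep(x, 3), c(250 * x, 240 * x, 260 * x))
  expect_equal(mod_r$slope, 250, tolerance = 1e-9)
  expect_error(fit_linear_range(c(1, 2, 3), c(1, 2, 3)), "5 distinct")
  set.seed(4)
  expect_error(
    fit_linear_range(x, sample(c(1e5, 1, 300, 2, 9e3, 80, 4e4, 6, 1e2, 77, 5))),
    "no linear window"
  )
})

test_that("linear-range fits are invariant to input row order", {
  mt <- small_calibration(seed = 21)
  d <- mt[mt$analyte == "Am" & mt$channel == "MS12" & mt$level_pmol > 0, ]
  ref <- fit_linear_range(d$level_pmol, d$peak_area)
  set.seed(1)
  perm <- sample(nrow(d))
  shuffled <- fit_linear_range(d$level_pmol[perm], d$peak_area[perm])
  expect_equal(shuffled, ref)
})

test_that("LOD/LOQ follow the 3-sigma/10-sigma blank rule", {
  expect_warning(res <- estimate_lod_loq(c(5, 5, 5), 100), "zero variance")
  expect_equal(unname(res), c(0, 0))
  blanks <- c(2, 5, 8)  # sd = 3
  expect_equal(estimate_lod_loq(blanks, 1000),
               c(lod = 0.009, loq = 0.03), tolerance = 1e-12)
  # Monte Carlo: simulated blank noise of sd 3 against slope rf = 1000
  m <- instrument_model(nucleosides = "Am", rf = 1000, sigma_add = 3,
                        drift_cv = 0)
  lods <- vapply(1:100, function(seed) {
    mt <- simulate_calibration(m, levels = c(0, 1), n_replicates = 8,
                               seed = seed)
    blank <- mt$peak_area[mt$level_pmol == 0 & mt$channel == "MS12"]
    estimate_lod_loq(blank, 1000)[["lod"]]
  }, 0)
  expect_lt(abs(mean(lods) / 0.009 - 1), 0.3)
})

test_that("rRFN fit is a weighted through-origin slope with guards", {
  x <- 10^seq(-2, 2, length.out = 8)
  fit <- fit_rrfn(x, 0.04538 * x)
  expect_equal(fit$rrfn, 0.04538, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  zero <- fit_rrfn(x, rep(0, 8))
  expect_equal(zero$rrfn, 0)
  expect_true(zero$flag_degenerate)
  expect_error(fit_rrfn(x, c(-1, 0.04538 * x[-1])), "negative NIF")
})

test_that("UVF fit recovers the UV response and is canonical-only", {
  x <- 10^seq(-1, 2, length.out = 7)
  expect_equal(fit_uvf(x, 500 * x, "G")$uvf, 500, tolerance = 1e-12)
  expect_error(fit_uvf(x, 500 * x, "Am"), "canonical")
  # simulated UV channel recovers the true response factor within 1%
  m <- instrument_model(seed = 2)
  mt <- simulate_calibration(m, nucleosides = c("G", "Am"), seed = 2)
  uv <- mt[mt$analyte == "G" & mt$channel == "UV254" & mt$level_pmol > 0, ]
  fit <- fit_uvf(uv$level_pmol, uv$peak_area, "G")
  expect_lt(abs(fit$uvf / m$uvf_true[["G"]] - 1), 0.01)
})

test_that("session stability is the percent RSD of per-session estimates", {
  expect_equal(session_stability(c(4, 4, 4)), 0)
  expect_equal(session_stability(c(9.8, 10.0, 10.2)), 2.0)
  expect_error(session_stability(7), "at least 2")
  expect_error(session_stability(c(-1, 1)), "mean")
})

test_that("rRFN recovers the reciprocal SIL-IS spike on simulated data", {
  for (seed in 1:3) {
    mt <- simulate_calibration(small_model(seed), nucleosides = c("Am", "Y"),
                               silis_pmol = 0.1, seed = seed)
    rf <- build_rf_table(mt)
    for (i in seq_len(nrow(rf$rf))) {
      expect_lt(abs(rf$rf$rrfn_pmol_inv[i] - 1 / 0.1),
                3 * rf$rf$se[i] + 1e-9)
    }
  }
})

test_that("NIF linear window contains the raw window and extends its top", {
  # noiseless-limit check of the structural claim: suppression shortens the
  # raw window at the top while the isotopomer ratio stays proportional
  m <- instrument_model(nucleosides = "Am", sigma_add = 0, cv_prop = 0,
                        drift_cv = 0)
  mt <- simulate_calibration(m, n_replicates = 1)
  rf <- build_rf_table(mt, blank_correct = FALSE)
  raw <- rf$models[rf$models$channel == "MS12", ]
  nif <- rf$models[rf$models$channel == "NIF", ]
  expect_lte(nif$linear_lo, raw$linear_lo)
  expect_gte(nif$linear_hi, raw$linear_hi)
  expect_gt(nif$decades, raw$decades)
  # under the default noise model the top-end extension persists
  for (seed in 4:6) {
    rfn <- build_rf_table(small_calibration(seed))
    m_raw <- rfn$models[rfn$models$channel == "MS12" &
                          rfn$models$nucleoside == "Am", ]
    m_nif <- rfn$models[rfn$models$channel == "NIF" &
                          rfn$models$nucleoside == "Am", ]
    expect_gte(m_nif$linear_hi, m_raw$linear_hi)
    expect_gte(m_nif$decades, m_raw$decades)
  }
})

test_that("shared drift inflates raw slopes but not the rRFN across sessions", {
  m <- instrument_model(nucleosides = "Am", drift_cv = 0.24, seed = 13)
  mt <- simulate_calibration(m, n_sessions = 6, seed = 13)
  # raw per-session response at a fixed mid-range level
  d <- mt[mt$channel == "MS12" & mt$level_pmol == 0.1, ]
  raw_by_session <- tapply(d$peak_area, d$session_id, mean)
  rf <- build_rf_table(mt)
  expect_gt(session_stability(raw_by_session), 5)
  expect_lt(rf$rf$session_rsd_pct, 2)
  expect_lt(rf$rf$session_rsd_pct, session_stability(raw_by_session))
})
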