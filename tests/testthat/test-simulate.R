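test_that("expected signals share suppression between isotopomer channels", {
  m <- small_model()
  # symmetry: equal amounts give equal means
  es <- expected_signals(m, 0.4, 0.4, "Am")
  expect_equal(es$ms12, es$ms13)
  # half-capacity point of the hyperbola
  es <- expected_signals(m, m$k_sat[["Am"]], 1e-9, "Am")
  expect_equal(es$ms12, m$rf[["Am"]] * m$k_sat[["Am"]] / 2, tolerance = 1e-6)
  # the 12C/13C mean ratio equals a12/a13 regardless of suppression depth
  deep <- instrument_model(nucleosides = "Am", k_sat = 0.01)
  none <- instrument_model(nucleosides = "Am", k_sat = 1e12)
  r_deep <- with(expected_signals(deep, 7, 1, "Am"), ms12 / ms13)
  r_none <- with(expected_signals(none, 7, 1, "Am"), ms12 / ms13)
  expect_equal(r_deep, 7)
  expect_equal(r_deep, r_none)
  expect_error(expected_signals(m, 1, 1, "m5C"), "not in the instrument model")
})

test_that("raw response is monotone but concave (sub-linear) in amount", {
  m <- small_model()
  a <- 10^seq(-3, 2, by = 0.25)
  s <- expected_signals(m, a, 0.1, "Am")$ms12
  expect_true(all(diff(s) > 0))
  # concavity: slope of the response decreases with amount
  sec <- diff(s) / diff(a)
  expect_true(all(diff(sec) < 0))
})

test_that("noiseless simulation reproduces expected signals exactly", {
  m <- instrument_model(nucleosides = c("Am", "G"), sigma_add = 0,
                        cv_prop = 0, drift_cv = 0, uv_cv = 0, seed = 5)
  lev <- c(0, 10^seq(-3, 1, by = 1))
  mt <- simulate_calibration(m, levels = lev, n_replicates = 2)
  for (l in lev) {
    es <- expected_signals(m, l, 0.1, "Am")
    got12 <- mt$peak_area[mt$analyte == "Am" & mt$channel == "MS12" &
                            mt$level_pmol == l]
    got13 <- mt$peak_area[mt$analyte == "Am" & mt$channel == "MS13" &
                            mt$level_pmol == l]
    expect_equal(got12, rep(es$ms12, 2))
    expect_equal(got13, rep(es$ms13, 2))
  }
})

test_that("replicate scatter at high signal matches the configured CV", {
  m <- instrument_model(nucleosides = "Am", drift_cv = 0, seed = 11)
  mt <- simulate_calibration(m, levels = c(0.01, 0.1, 1), n_replicates = 60)
  for (l in c(0.1, 1)) {
    x <- mt$peak_area[mt$channel == "MS12" & mt$level_pmol == l]
    cv <- sd(x) / mean(x)
    expect_gt(cv, m$cv_prop * 0.6)
    expect_lt(cv, m$cv_prop * 1.6)
  }
})

test_that("session drift moves raw signals but cancels in the isotopomer ratio", {
  m <- instrument_model(nucleosides = "Am", drift_cv = 0.24, cv_prop = 0,
                        sigma_add = 0, seed = 3)
  mt <- simulate_calibration(m, levels = c(0.1, 1), n_replicates = 2,
                             n_sessions = 2)
  raw <- nif <- list()
  for (s in c("s01", "s02")) {
    d <- mt[mt$session_id == s & mt$level_pmol == 1, ]
    raw[[s]] <- mean(d$peak_area[d$channel == "MS12"])
    nif[[s]] <- mean(d$peak_area[d$channel == "MS12"]) /
      mean(d$peak_area[d$channel == "MS13"])
  }
  expect_false(isTRUE(all.equal(raw$s01, raw$s02, tolerance = 1e-6)))
  expect_equal(nif$s01, nif$s02, tolerance = 1e-12)
})

test_that("simulation is byte-identical for a fixed seed", {
  a <- small_calibration(seed = 42)
  b <- small_calibration(seed = 42)
  expect_identical(a, b)
  sim1 <- simulate_digest(small_model(7), trub_truth(), seed = 7)
  sim2 <- simulate_digest(small_model(7), trub_truth(), seed = 7)
  expect_identical(sim1$measurements, sim2$measurements)
})

test_that("digest simulation reflects the sample truth", {
  m <- small_model(9)
  # zero modification: 12C channel at baseline noise only
  t0 <- sample_truth(amounts_12c = c(Y = 0))
  sim0 <- simulate_digest(m, t0, seed = 9)
  ms12 <- sim0$measurements
  ms12 <- ms12$peak_area[ms12$analyte == "Y" & ms12$channel == "MS12" &
                           startsWith(ms12$run_id, "sample")]
  expect_true(all(ms12 < 20 * m$sigma_add))
  # doubling the RNA amount doubles every truth amount and UV contribution
  t1 <- trub_truth(rna_pmol = 13.2)
  t2 <- trub_truth(rna_pmol = 26.4)
  expect_equal(2 * t1$amounts_12c, t2$amounts_12c)
  mq <- instrument_model(nucleosides = c("Y", "C", "U", "G", "A"),
                         sigma_add = 0, cv_prop = 0, drift_cv = 0, uv_cv = 0)
  uv_g <- function(truth) {
    sim <- simulate_digest(mq, truth, n_replicates = 1,
                           include_silis_blank = TRUE)
    mt <- sim$measurements
    tot <- mt$peak_area[mt$analyte == "G" & mt$channel == "UV254" &
                          startsWith(mt$run_id, "sample")]
    sil <- mt$peak_area[mt$analyte == "G" & mt$channel == "UV254" &
                          startsWith(mt$run_id, "silis_blank")]
    tot - sil
  }
  expect_equal(uv_g(t2), 2 * uv_g(t1), tolerance = 1e-12)
  # unknown nucleoside is reported by name
  expect_error(simulate_digest(m, sample_truth(amounts_12c = c(zzz = 1))),
               "zzz")
})

test_that("truth construction validates its inputs", {
  expect_error(sample_truth(rna_pmol = 5), "together")
  expect_error(sample_truth(), "required")
  tr <- trub_truth(occupancy = 0.5)
  expect_equal(unname(tr$amounts_12c["Y"]), 13.2 * 0.5)
})
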