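test_that("absolute amount is NIF over rRFN with replicate propagation", {
  expect_equal(absolute_amount(0, 1000, 10)$pmol, 0)
  # a NIF numerically equal to the rRFN corresponds to exactly 1 pmol
  expect_equal(absolute_amount(0.04538 * 5e4, 5e4, 0.04538)$pmol, 1,
               tolerance = 1e-12)
  res <- absolute_amount(c(98, 100, 102), c(100, 100, 100), 10)
  expect_equal(res$pmol, 0.1, tolerance = 1e-12)
  expect_equal(res$n, 3)
  expect_equal(res$se, sd(c(0.098, 0.100, 0.102)) / sqrt(3))
  expect_error(absolute_amount(1, 1, NA_real_, "D"), "D")
  expect_error(absolute_amount(1, 0, 10), "SIL-IS")
})

test_that("absolute amount inverts the simulator exactly in the noiseless limit", {
  for (k in c(0.05, 5, 1e9)) {
    m <- instrument_model(nucleosides = "Y", k_sat = k)
    for (drift in c(0.3, 1, 2.4)) {
      for (a12 in c(1e-4, 0.5, 13.2, 80)) {
        es <- expected_signals(m, a12, 0.1, "Y")
        rrfn <- 1 / 0.1  # true response factor for a 0.1 pmol spike
        expect_equal(absolute_amount(es$ms12 * drift, es$ms13 * drift,
                                     rrfn)$pmol,
                     a12, tolerance = 1e-12)
      }
    }
  }
})

test_that("UV-based RNA amount applies the SIL-IS-corrected guanosine area", {
  # 303.6 pmol of sample guanosine over 23 G residues -> 13.2 pmol RNA
  uvf <- 800
  silis_uv <- uvf * 70
  total_uv <- uvf * (303.6 + 70)
  expect_equal(rna_amount_from_uv(total_uv, silis_uv, uvf, 23), 13.2,
               tolerance = 1e-12)
  expect_equal(rna_amount_from_uv(silis_uv, silis_uv, uvf, 23), 0)
  expect_error(rna_amount_from_uv(100, 200, uvf, 23), "overspiked")
  # linear in corrected area, inverse-linear in residue count
  base <- rna_amount_from_uv(total_uv, silis_uv, uvf, 23)
  expect_equal(rna_amount_from_uv(silis_uv + 2 * (total_uv - silis_uv),
                                  silis_uv, uvf, 23), 2 * base)
  expect_equal(rna_amount_from_uv(total_uv, silis_uv, uvf, 46), base / 2)
})

test_that("modification yield covers per-molecule, parent-% and mol-% forms", {
  y <- modification_yield(5, 5, sites = 1)
  expect_equal(y$per_molecule, 1)
  expect_equal(y$occupancy, 1)
  y2 <- modification_yield(6.6, 13.2, sites = 2, parent_count = 18,
                           total_residues = 76)
  expect_equal(y2$per_molecule, 0.5)
  expect_equal(y2$occupancy, 0.25)
  expect_equal(y2$pct_of_parent, 100 * 6.6 / (13.2 * 18))
  expect_equal(y2$mol_pct, 100 * 0.5 / 76)
  expect_true(is.na(modification_yield(1, 2)$mol_pct))
})

test_that("quantification pipeline recovers simulated digests", {
  m <- instrument_model(nucleosides = c(mods10, canonical_nucleosides()),
                        seed = 31)
  rf <- build_rf_table(simulate_calibration(m, seed = 31))
  # known 0.5 pmol m5C recovered within 5%
  tr <- sample_truth(rna_pmol = 10, sequence_counts = trna_counts[1:4],
                     modifications = data.frame(
                       nucleoside = c("m5C", "Am"), sites = c(1, 1),
                       occupancy = c(0.05, 0.75)))
  sim <- simulate_digest(m, tr, seed = 32)
  qr <- quantify_sample(sim$measurements, rf, counts = trna_counts)
  m5c <- qr$amounts[qr$amounts$nucleoside == "m5C", ]
  expect_lt(abs(m5c$pmol / 0.5 - 1), 0.05)
  # RNA amount from UV within 2%
  expect_lt(abs(qr$rna_pmol / 10 - 1), 0.02)
  # simulated occupancy 0.75 at one site recovered within 0.02
  am <- qr$yields[qr$yields$nucleoside == "Am", ]
  expect_lt(abs(am$occupancy - 0.75), 0.02)
  # occupancy of a full single site never exceeds 1 by more than noise
  full <- simulate_digest(m, trub_truth(), seed = 33)
  qr_full <- quantify_sample(full$measurements, rf, counts = trna_counts)
  occ <- qr_full$yields$occupancy[qr_full$yields$nucleoside == "Y"]
  expect_lt(occ, 1 + 3 * 0.02)
  expect_gt(occ, 1 - 3 * 0.02)
})

test_that("quantification validates SIL-IS presence and calibration coverage", {
  m <- small_model(35)
  sim <- simulate_digest(m, trub_truth(), seed = 35)
  rf <- build_rf_table(simulate_calibration(m, seed = 35))
  no13 <- sim$measurements[sim$measurements$channel != "MS13", ]
  expect_error(quantify_sample(no13, rf), "SIL-IS missing")
  # nucleoside without rRFN is reported by name
  rf_empty <- rf
  rf_empty$rf <- rf$rf[rf$rf$nucleoside != "Y", ]
  expect_warning(quantify_sample(sim$measurements, rf_empty), "Y")
})

test_that("spike-in recovery verifies the response factor", {
  fake <- function(pmol) {
    structure(list(amounts = tibble::tibble(nucleoside = "Y", pmol = pmol)),
              class = "quant_result")
  }
  same <- spike_check(fake(13), fake(13), 0.1, "Y")
  expect_equal(same$recovery, 0)
  expect_false(same$pass)
  exact <- spike_check(fake(13), fake(13.1), 0.1, "Y")
  expect_equal(exact$recovery, 1)
  expect_true(exact$pass)
  expect_error(spike_check(fake(1), fake(2), 0.1, "Am"), "not quantified")
})

test_that("spike recovery is near-unity across simulated repeats", {
  m <- instrument_model(nucleosides = c("Y", canonical_nucleosides()),
                        seed = 40)
  rf <- build_rf_table(simulate_calibration(m, seed = 40))
  base <- sample_truth(amounts_12c = c(Y = 0.4))
  spiked <- sample_truth(amounts_12c = c(Y = 0.5))
  recov <- vapply(1:200, function(seed) {
    q1 <- quantify_sample(
      simulate_digest(m, base, n_replicates = 5, seed = seed)$measurements, rf)
    q2 <- quantify_sample(
      simulate_digest(m, spiked, n_replicates = 5,
                      seed = seed + 1000L)$measurements, rf)
    spike_check(q1, q2, 0.1, "Y", tolerance = 0.1)$recovery
  }, 0)
  expect_gte(mean(recov >= 0.9 & recov <= 1.1), 0.95)
})
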