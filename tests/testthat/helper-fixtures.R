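# Shared fixtures, built in code at test time.

# Instrument restricted to one modified nucleoside plus the canonicals:
# enough for most calibration tests and fast to simulate.
small_model <- function(seed = 1L, ...) {
  instrument_model(nucleosides = c("Am", "Y", "C", "U", "G", "A"),
                   seed = seed, ...)
}

# Calibration table + fitted response factors for the small model.
small_calibration <- function(seed = 1L, ...) {
  simulate_calibration(small_model(seed), seed = seed, ...)
}

# The ten externally calibratable modified nucleosides.
mods10 <- c("Cm", "m5C", "Y", "m5U", "m7G", "Gm", "m6A", "Am", "m62A", "I")

# Residue counts of the 76-residue tRNA-like transcript used by trub_truth().
trna_counts <- c(C = 15, U = 18, G = 23, A = 20, total = 76)

# Exact monoisotopic [M+H]+ oracle, independent of the registry code path:
# plain arithmetic over atomic masses.
oracle_mz <- function(nC, nH, nN, nO, nS = 0, c13 = FALSE) {
  mC <- if (c13) 13.003355 else 12
  nC * mC + nH * 1.007825 + nN * 14.003074 + nO * 15.994915 +
    nS * 31.972071 + 1.007276
}

# Brute-force isotopologue oracle: enumerate all 2^n labelings of the carbon
# atoms and accumulate the probability of each 13C count.
enumerate_pattern <- function(n, p13) {
  probs <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    k <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    probs[k + 1] <- probs[k + 1] + p13^k * (1 - p13)^(n - k)
  }
  probs / sum(probs)
}
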