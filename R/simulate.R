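# Seeded synthetic instrument: saturating MS response with ion suppression
# shared between co-eluting isotopomers, inter-session drift, proportional +
# additive noise, and a linear UV channel.

#' Construct a synthetic instrument model
#'
#' Describes the detector used by the simulator. The MS response of an
#' analyte is hyperbolic in the total co-eluting amount: for injected amounts
#' `a12` (unlabeled analyte) and `a13` (its 13C isotopomer from the SIL-IS),
#' the shared suppression factor is `phi = 1 / (1 + (a12 + a13) / k_sat)` and
#' the mean signals are `rf * a12 * phi` and `rf * a13 * phi`. Because the
#' isotopomers co-elute and ionize identically, suppression and session drift
#' multiply both channels equally and cancel in their ratio (the NIF); this
#' is the mechanism the whole workflow relies on.
#'
#' Noise model per injection and channel: multiplicative
#' `(1 + N(0, cv_prop))` plus a strictly positive additive background drawn
#' from a lognormal with mean and standard deviation `sigma_add` (peak
#' integration reports non-negative areas, so a Gaussian additive term is not
#' used; the blank standard deviation still equals `sigma_add`). Each session
#' draws one lognormal drift factor (mean 1, coefficient of variation
#' `drift_cv`) applied to `rf` in both MS channels of a nucleoside. The UV
#' channel is linear in amount with multiplicative noise `uv_cv` and no
#' drift.
#'
#' @param nucleosides Character vector of nucleoside symbols the instrument
#'   responds to (default: the full default registry).
#' @param rf MS response factor(s), signal counts per pmol; scalar or named
#'   vector over `nucleosides`.
#' @param k_sat Suppression capacity in pmol (scalar or named vector); the
#'   co-eluting amount at which the response has dropped to half.
#' @param sigma_add Additive baseline noise SD, signal counts.
#' @param cv_prop Proportional noise CV per injection and channel.
#' @param drift_cv Inter-session lognormal drift CV; scalar or named vector.
#' @param uv_cv UV channel multiplicative noise CV.
#' @param uvf_true UV response, area per pmol, named over the canonical
#'   nucleosides.
#' @param seed Integer seed used by the simulation functions by default.
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(nucleosides = names(default_registry()),
                             rf = 1e6, k_sat = 5, sigma_add = 3,
                             cv_prop = 0.01, drift_cv = 0.24, uv_cv = 0.005,
                             uvf_true = c(C = 450, U = 600, G = 800, A = 900),
                             seed = 1L) {
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(nucleosides)), nucleosides)
    }
    if (!all(nucleosides %in% names(x))) {
      stop("'", what, "' missing entries for: ",
           paste(setdiff(nucleosides, names(x)), collapse = ", "), call. = FALSE)
    }
    x[nucleosides]
  }
  rf <- expand(rf, "rf")
  k_sat <- expand(k_sat, "k_sat")
  drift_cv <- expand(drift_cv, "drift_cv")
  stopifnot(all(rf > 0), all(k_sat > 0), all(uvf_true > 0),
            sigma_add >= 0, cv_prop >= 0, cv_prop < 1,
            all(drift_cv >= 0), all(drift_cv < 1), uv_cv >= 0, uv_cv < 1)
  structure(
    list(nucleosides = nucleosides, rf = rf, k_sat = k_sat,
         sigma_add = sigma_add, cv_prop = cv_prop, drift_cv = drift_cv,
         uv_cv = uv_cv, uvf_true = uvf_true, seed = as.integer(seed)),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(paste0("<instrument_model> %d nucleosides; rf ~%g counts/pmol; ",
                     "k_sat ~%g pmol; sigma_add %g; cv_prop %g; drift_cv ~%g; ",
                     "uv_cv %g; seed %d\n"),
              length(x$nucleosides), stats::median(x$rf), stats::median(x$k_sat),
              x$sigma_add, x$cv_prop, stats::median(x$drift_cv), x$uv_cv, x$seed))
  invisible(x)
}

#' Noise-free expected MS signals for an isotopomer pair
#'
#' Mean 12C and 13C signals for co-injected amounts `a12` and `a13` of a
#' nucleoside, with the suppression factor shared between both channels. The
#' ratio of the two means equals `a12 / a13` exactly for any amounts and any
#' `k_sat`: suppression cancels in the isotopomer ratio.
#'
#' @param model An [instrument_model()].
#' @param a12,a13 Injected amounts (pmol) of the unlabeled analyte and of its
#'   13C isotopomer; vectors are recycled.
#' @param nucleoside Nucleoside symbol.
#' @return A list with numeric vectors `ms12` and `ms13`.
#' @export
expected_signals <- function(model, a12, a13, nucleoside) {
  stopifnot(inherits(model, "instrument_model"), all(a12 >= 0), all(a13 >= 0))
  if (!nucleoside %in% model$nucleosides) {
    stop("nucleoside '", nucleoside, "' is not in the instrument model",
         call. = FALSE)
  }
  rf <- model$rf[[nucleoside]]
  k <- model$k_sat[[nucleoside]]
  phi <- 1 / (1 + (a12 + a13) / k)
  list(ms12 = rf * a12 * phi, ms13 = rf * a13 * phi)
}

# Lognormal draws with a given mean and coefficient of variation.
.rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0 || mean <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Apply the per-injection noise model to a vector of expected signals.
.noisy_signal <- function(expected, cv_prop, sigma_add) {
  n <- length(expected)
  out <- expected * (1 + stats::rnorm(n, 0, cv_prop))
  if (sigma_add > 0) out <- out + .rlnorm_cv(n, sigma_add, 1)
  pmax(out, 0)
}

#' Default calibration level grid
#'
#' Fifteen half-decade injected-amount levels from 0.01 fmol to 100 pmol,
#' plus a blank, mirroring a 15-solution serial dilution over seven decades.
#'
#' @param include_blank Prepend a level of 0 pmol.
#' @return Numeric vector of pmol levels, ascending.
#' @export
calibration_levels <- function(include_blank = TRUE) {
  lev <- 10^seq(-5, 2, by = 0.5)
  if (include_blank) lev <- c(0, lev)
  lev
}

#' Simulate a calibration series
#'
#' Generates the measurement table of a dilution-series experiment: for every
#' session, level and replicate injection, MS rows for the 12C analyte and
#' its constant SIL-IS 13C isotopomer, and (for canonical nucleosides) UV
#' rows modeling the SIL-IS-free calibration set. One drift factor per
#' session and nucleoside multiplies the MS response of both channels.
#' Deterministic given `seed`.
#'
#' @param model An [instrument_model()].
#' @param levels Injected 12C amounts in pmol, ascending; a level of 0 is a
#'   blank. Default [calibration_levels()].
#' @param silis_pmol Constant SIL-IS spike per injection (pmol of the 13C
#'   isotopomer); scalar or named vector over nucleosides.
#' @param n_replicates Injections per level and session.
#' @param n_sessions Number of measurement sessions (each with its own drift).
#' @param nucleosides Subset of model nucleosides to simulate.
#' @param seed Integer seed; defaults to the model seed.
#' @return A measurement table (tibble) with columns `run_id`, `session_id`,
#'   `analyte`, `channel` (`MS12`/`MS13`/`UV254`), `peak_area`, `level_pmol`,
#'   `replicate`.
#' @export
simulate_calibration <- function(model, levels = calibration_levels(),
                                 silis_pmol = 0.1, n_replicates = 3,
                                 n_sessions = 1,
                                 nucleosides = model$nucleosides,
                                 seed = model$seed) {
  stopifnot(inherits(model, "instrument_model"))
  if (length(levels) == 0) stop("'levels' must be non-empty", call. = FALSE)
  if (is.unsorted(levels) || any(levels < 0)) {
    stop("'levels' must be ascending and non-negative", call. = FALSE)
  }
  if (length(silis_pmol) == 1L && is.null(names(silis_pmol))) {
    silis_pmol <- stats::setNames(rep(silis_pmol, length(nucleosides)), nucleosides)
  }
  stopifnot(all(nucleosides %in% model$nucleosides),
            all(nucleosides %in% names(silis_pmol)),
            all(silis_pmol > 0))
  canon <- intersect(nucleosides, canonical_nucleosides())

  set.seed(seed)
  out <- vector("list", n_sessions * length(nucleosides))
  idx <- 0L
  for (s in seq_len(n_sessions)) {
    session_id <- sprintf("s%02d", s)
    for (nuc in nucleosides) {
      drift <- .rlnorm_cv(1, 1, model$drift_cv[[nuc]])
      a13 <- silis_pmol[[nuc]]
      grid <- expand.grid(level_i = seq_along(levels),
                          replicate = seq_len(n_replicates))
      a12 <- levels[grid$level_i]
      exp_sig <- expected_signals(model, a12, a13, nuc)
      ms12 <- .noisy_signal(exp_sig$ms12 * drift, model$cv_prop, model$sigma_add)
      ms13 <- .noisy_signal(exp_sig$ms13 * drift, model$cv_prop, model$sigma_add)
      run_id <- sprintf("cal-%s-l%02d-r%d", session_id, grid$level_i, grid$replicate)
      rows <- tibble::tibble(
        run_id = rep(run_id, 2),
        session_id = session_id,
        analyte = nuc,
        channel = rep(c("MS12", "MS13"), each = nrow(grid)),
        peak_area = c(ms12, ms13),
        level_pmol = rep(a12, 2),
        replicate = rep(grid$replicate, 2)
      )
      if (nuc %in% canon) {
        uv <- pmax(model$uvf_true[[nuc]] * a12 *
                     (1 + stats::rnorm(nrow(grid), 0, model$uv_cv)), 0)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          run_id = run_id, session_id = session_id, analyte = nuc,
          channel = "UV254", peak_area = uv, level_pmol = a12,
          replicate = grid$replicate
        ))
      }
      idx <- idx + 1L
      out[[idx]] <- rows
    }
  }
  res <- dplyr::bind_rows(out)
  res[order(res$session_id, res$analyte, res$level_pmol, res$replicate,
            res$channel), , drop = FALSE]
}

#' Construct the ground truth of a simulated RNA digest
#'
#' Describes one digested RNA sample: the injected RNA amount, the residue
#' composition of its sequence, the modified sites and their occupancies, and
#' the SIL-IS spike composition. Modified-nucleoside amounts are
#' `rna_pmol * sites * occupancy` unless given explicitly via `amounts_12c`.
#'
#' @param rna_pmol Injected RNA amount in pmol (optional when explicit
#'   `amounts_12c` are given).
#' @param sequence_counts Named integer vector of canonical residue counts
#'   (`C`, `U`, `G`, `A`) of the RNA sequence.
#' @param modifications Data frame with columns `nucleoside`, `sites`,
#'   `occupancy` (fraction of molecules modified per site).
#' @param amounts_12c Optional named vector: explicit pmol per modified
#'   nucleoside, overriding the site-based construction.
#' @param silis_mod_pmol SIL-IS spike of each modified nucleoside (pmol).
#' @param silis_canonical_pmol SIL-IS amount of each canonical nucleoside
#'   (pmol); the SIL-IS is a total-RNA digest, so canonicals dominate it.
#' @return Object of class `sample_truth`.
#' @export
sample_truth <- function(rna_pmol = NULL, sequence_counts = NULL,
                         modifications = NULL, amounts_12c = NULL,
                         silis_mod_pmol = 0.1, silis_canonical_pmol = 70) {
  if (is.null(sequence_counts) != is.null(rna_pmol)) {
    stop("'rna_pmol' and 'sequence_counts' must be given together", call. = FALSE)
  }
  if (is.null(amounts_12c)) {
    if (is.null(modifications) || is.null(rna_pmol)) {
      stop("either 'amounts_12c' or ('rna_pmol' + 'modifications') is required",
           call. = FALSE)
    }
    amounts_12c <- stats::setNames(
      rna_pmol * modifications$sites * modifications$occupancy,
      modifications$nucleoside
    )
  }
  stopifnot(all(amounts_12c >= 0), silis_mod_pmol > 0, silis_canonical_pmol > 0)
  silis <- stats::setNames(rep(silis_mod_pmol, length(amounts_12c)),
                           names(amounts_12c))
  structure(
    list(rna_pmol = rna_pmol, sequence_counts = sequence_counts,
         modifications = modifications, amounts_12c = amounts_12c,
         silis_amounts = silis, silis_canonical_pmol = silis_canonical_pmol),
    class = "sample_truth"
  )
}

#' Simulate the measurement of a digested RNA sample
#'
#' Produces MS rows (12C + 13C channel) for every modified nucleoside of the
#' truth and UV rows for the canonical nucleosides, where the UV area covers
#' sample plus SIL-IS material (the SIL-IS contributes to UV and must be
#' subtracted downstream). A SIL-IS-only blank run is appended so that the
#' quantification can measure that contribution. Deterministic given `seed`.
#'
#' @param model An [instrument_model()].
#' @param truth A [sample_truth()].
#' @param n_replicates Replicate injections.
#' @param include_silis_blank Append a SIL-IS-only run (`run "silis_blank"`).
#' @param seed Integer seed; defaults to the model seed.
#' @return List with `measurements` (measurement table; sample rows carry
#'   `run_id` prefix `"sample"`, the blank `"silis_blank"`) and `truth`
#'   (tibble `nucleoside`, `true_pmol`, plus attribute `rna_pmol`).
#' @export
simulate_digest <- function(model, truth, n_replicates = 3,
                            include_silis_blank = TRUE, seed = model$seed) {
  stopifnot(inherits(model, "instrument_model"), inherits(truth, "sample_truth"))
  missing_nuc <- setdiff(names(truth$amounts_12c), model$nucleosides)
  if (length(missing_nuc) > 0) {
    stop("nucleoside(s) absent from the instrument model: ",
         paste(missing_nuc, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  session_id <- "s01"
  runs <- list(sample = TRUE)
  if (include_silis_blank) runs$silis_blank <- FALSE
  out <- list()
  for (run in names(runs)) {
    with_sample <- runs[[run]]
    drift <- .rlnorm_cv(1, 1, stats::median(model$drift_cv))
    run_id <- sprintf("%s-r%d", run, seq_len(n_replicates))
    for (nuc in names(truth$amounts_12c)) {
      a12 <- if (with_sample) truth$amounts_12c[[nuc]] else 0
      a13 <- truth$silis_amounts[[nuc]]
      es <- expected_signals(model, a12, a13, nuc)
      out[[length(out) + 1L]] <- tibble::tibble(
        run_id = rep(run_id, 2), session_id = session_id, analyte = nuc,
        channel = rep(c("MS12", "MS13"), each = n_replicates),
        peak_area = c(
          .noisy_signal(rep(es$ms12 * drift, n_replicates), model$cv_prop, model$sigma_add),
          .noisy_signal(rep(es$ms13 * drift, n_replicates), model$cv_prop, model$sigma_add)
        ),
        level_pmol = NA_real_,
        replicate = rep(seq_len(n_replicates), 2)
      )
    }
    for (nuc in canonical_nucleosides()) {
      sample_pmol <- if (with_sample && !is.null(truth$rna_pmol)) {
        truth$rna_pmol * truth$sequence_counts[[nuc]]
      } else 0
      tot <- sample_pmol + truth$silis_canonical_pmol
      uv <- pmax(model$uvf_true[[nuc]] * tot *
                   (1 + stats::rnorm(n_replicates, 0, model$uv_cv)), 0)
      out[[length(out) + 1L]] <- tibble::tibble(
        run_id = run_id, session_id = session_id, analyte = nuc,
        channel = "UV254", peak_area = uv, level_pmol = NA_real_,
        replicate = seq_len(n_replicates)
      )
    }
  }
  truth_tbl <- tibble::tibble(
    nucleoside = names(truth$amounts_12c),
    true_pmol = unname(truth$amounts_12c)
  )
  attr(truth_tbl, "rna_pmol") <- truth$rna_pmol
  list(measurements = dplyr::bind_rows(out), truth = truth_tbl)
}

#' Ground truth of the pseudouridine synthase turnover scenario
#'
#' A tRNA-like in vitro assay: a 76-residue transcript (23 G residues)
#' injected at 13.2 pmol, carrying one pseudouridine site at full occupancy
#' after complete enzymatic conversion.
#'
#' @param occupancy Fraction of molecules pseudouridylated at the single site.
#' @param rna_pmol Injected RNA amount in pmol.
#' @return A [sample_truth()].
#' @export
trub_truth <- function(occupancy = 1.0, rna_pmol = 13.2) {
  sample_truth(
    rna_pmol = rna_pmol,
    sequence_counts = c(C = 15, U = 18, G = 23, A = 20),
    modifications = data.frame(nucleoside = "Y", sites = 1,
                               occupancy = occupancy)
  )
}
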