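# Relative quantification between samples: double-normalized modification
# levels, fold changes and background flagging.

#' Double-normalized modification level
#'
#' Each modified-nucleoside MS signal is first divided by the signal of its
#' co-measured 13C isotopomer (removing suppression, matrix and drift
#' effects) and then by the UV-signal sum of the four canonical nucleosides
#' (removing differences in injected sample amount). The result is a
#' dimensionless, loading- and drift-invariant modification level.
#'
#' @param signal_12c,signal_13c MS peak areas of the analyte and its
#'   isotopomer.
#' @param uv_canonical_sum Sum of the UV areas of the four canonical
#'   nucleosides of the same run (> 0).
#' @return Dimensionless level (vectorized).
#' @export
normalized_level <- function(signal_12c, signal_13c, uv_canonical_sum) {
  if (any(uv_canonical_sum <= 0)) {
    stop("UV canonical sum must be positive", call. = FALSE)
  }
  compute_nif(signal_12c, signal_13c) / uv_canonical_sum
}

#' Fold change between two modification levels
#'
#' Ratio of the level in sample 1 to sample 2; values below 1 mean the
#' modification is higher in sample 2. A zero denominator yields `NA` (the
#' fold change is undefined, not infinite) and should be flagged by the
#' caller.
#'
#' @param level_1,level_2 Normalized levels.
#' @return `level_1 / level_2`, or `NA` where `level_2` is 0.
#' @export
fold_change <- function(level_1, level_2) {
  stopifnot(all(level_1 >= 0, na.rm = TRUE), all(level_2 >= 0, na.rm = TRUE))
  out <- ifelse(level_2 == 0, NA_real_, level_1 / level_2)
  out
}

#' Flag background-level nucleosides
#'
#' A fold change between two trace-level signals is an artifact of background
#' noise. A nucleoside is flagged as background when its absolute level
#' (moles per mole RNA) is below `threshold` in all compared samples; its
#' fold change is retained but not interpretable.
#'
#' @param abs_levels Numeric matrix or data frame, nucleosides in rows,
#'   samples in columns: absolute per-molecule levels.
#' @param threshold Background threshold in mol per mol RNA (default 0.01).
#' @return Named logical vector.
#' @export
flag_background <- function(abs_levels, threshold = 0.01) {
  m <- as.matrix(abs_levels)
  flags <- apply(m, 1, function(r) all(!is.na(r) & r < threshold))
  flags
}

# Median normalized level of each modified analyte in one sample run.
.sample_levels <- function(mt, run_prefix) {
  d <- mt[startsWith(mt$run_id, run_prefix), , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for run '", run_prefix, "'", call. = FALSE)
  canon <- canonical_nucleosides()
  uv <- d[d$channel == "UV254", , drop = FALSE]
  missing_uv <- setdiff(canon, unique(uv$analyte))
  if (length(missing_uv) > 0) {
    stop("UV rows missing for canonical nucleoside(s): ",
         paste(missing_uv, collapse = ", "), call. = FALSE)
  }
  uv_sum <- sum(vapply(canon, function(b)
    stats::median(uv$peak_area[uv$analyte == b]), 0))
  analytes <- setdiff(unique(d$analyte[d$channel == "MS12"]), canon)
  lv <- vapply(analytes, function(nuc) {
    s12 <- d$peak_area[d$analyte == nuc & d$channel == "MS12"]
    s13 <- d$peak_area[d$analyte == nuc & d$channel == "MS13"]
    if (length(s13) == 0) {
      stop("MS13 rows missing for '", nuc, "': SIL-IS missing", call. = FALSE)
    }
    stats::median(normalized_level(s12, s13, uv_sum))
  }, 0)
  stats::setNames(lv, analytes)
}

#' Compare modification levels between samples
#'
#' Computes the double-normalized level of every modified nucleoside in each
#' sample, fold changes of every sample against a designated reference
#' sample, and -- when a response-factor table and residue counts are
#' available -- the absolute per-molecule levels used to flag fold changes
#' that arise from background noise.
#'
#' @param samples Named list of measurement tables, one per sample. Each must
#'   contain the sample run (prefix `sample_run`) and, for absolute levels, a
#'   SIL-IS-only run.
#' @param rf Optional `rf_table` enabling absolute quantification.
#' @param counts Optional residue counts (see [quantify_sample()]).
#' @param reference_sample Name or index of the reference sample (fold
#'   changes are reference-relative; the reference itself gets 1).
#' @param threshold Background threshold in mol/mol RNA.
#' @param sample_run,silis_run Run-id prefixes (see [quantify_sample()]).
#' @param registry Nucleoside registry.
#' @return A tibble with one row per (nucleoside, sample): `nucleoside`,
#'   `sample`, `level`, `fold_change` (vs the reference sample),
#'   `abs_per_molecule` (`NA` without `rf`), `background`.
#' @export
compare_samples <- function(samples, rf = NULL, counts = NULL,
                            reference_sample = 1, threshold = 0.01,
                            sample_run = "sample", silis_run = "silis_blank",
                            registry = default_registry()) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  ref_name <- if (is.numeric(reference_sample)) {
    names(samples)[reference_sample]
  } else reference_sample
  stopifnot(ref_name %in% names(samples))
  levels <- lapply(samples, function(mt)
    .sample_levels(validate_measurements(mt), sample_run))
  analytes <- Reduce(intersect, lapply(levels, names))
  abs_levels <- NULL
  if (!is.null(rf) && !is.null(counts)) {
    abs_levels <- sapply(samples, function(mt) {
      qr <- quantify_sample(mt, rf, counts = counts, registry = registry,
                            sample_run = sample_run, silis_run = silis_run)
      pm <- stats::setNames(qr$yields$per_molecule, qr$yields$nucleoside)
      pm[analytes]
    })
    rownames(abs_levels) <- analytes
    bg <- flag_background(abs_levels, threshold)
  } else {
    bg <- stats::setNames(rep(NA, length(analytes)), analytes)
  }
  rows <- lapply(names(samples), function(sn) {
    tibble::tibble(
      nucleoside = analytes,
      sample = sn,
      level = unname(levels[[sn]][analytes]),
      fold_change = fold_change(unname(levels[[sn]][analytes]),
                                unname(levels[[ref_name]][analytes])),
      abs_per_molecule = if (is.null(abs_levels)) NA_real_ else
        unname(abs_levels[analytes, sn]),
      background = unname(bg[analytes])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_sample") <- ref_name
  out
}

#' Write a two-sample fold-change table as CSV
#'
#' Pivots the output of [compare_samples()] for a pair of samples to the wide
#' layout `nucleoside, level_1, level_2, fold_change, abs_1, abs_2,
#' background_flag`, where `fold_change` is sample 1 over sample 2.
#'
#' @param fc Output of [compare_samples()] for exactly two samples, with
#'   sample 2 as the reference.
#' @param path Output CSV path.
#' @return The wide tibble, invisibly.
#' @export
write_fold_change_table <- function(fc, path) {
  sn <- unique(fc$sample)
  stopifnot(length(sn) == 2)
  ref <- attr(fc, "reference_sample")
  other <- setdiff(sn, ref)
  a <- fc[fc$sample == other, , drop = FALSE]
  b <- fc[fc$sample == ref, , drop = FALSE]
  b <- b[match(a$nucleoside, b$nucleoside), , drop = FALSE]
  wide <- tibble::tibble(
    nucleoside = a$nucleoside,
    level_1 = a$level, level_2 = b$level,
    fold_change = a$fold_change,
    abs_1 = a$abs_per_molecule, abs_2 = b$abs_per_molecule,
    background_flag = a$background
  )
  .write_csv_full(wide, path)
  invisible(wide)
}
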