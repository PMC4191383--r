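# Absolute quantification: internal-standard amounts, UV-based RNA amount,
# modification yields, turnover and spike-in verification.

#' Absolute amount from the isotopomer signal pair
#'
#' The core quantification step: the measured NIF divided by the relative
#' response factor gives the injected amount,
#' `pmol = signal_12C / (rRFN * signal_13C)`. When replicate signal pairs are
#' supplied, the replicate spread is propagated to a standard error of the
#' mean.
#'
#' @param signal_12c,signal_13c Peak areas (replicate vectors of equal
#'   length; `signal_13c` must be positive).
#' @param rrfn Relative response factor in 1/pmol (> 0). `NA` or missing
#'   values signal a nucleoside without external calibration and raise an
#'   error.
#' @param nucleoside Optional label used in error messages.
#' @return List with `pmol` (mean over replicates), `se` (standard error;
#'   `NA` for a single replicate) and `n`.
#' @export
absolute_amount <- function(signal_12c, signal_13c, rrfn,
                            nucleoside = NA_character_) {
  if (length(rrfn) != 1 || is.na(rrfn) || rrfn <= 0) {
    stop("no valid rRFN available for nucleoside(s): ",
         ifelse(is.na(nucleoside), "<unnamed>", nucleoside),
         " (no external calibration possible)", call. = FALSE)
  }
  nif <- compute_nif(signal_12c, signal_13c)
  amounts <- nif / rrfn
  n <- length(amounts)
  list(pmol = mean(amounts),
       se = if (n > 1) stats::sd(amounts) / sqrt(n) else NA_real_,
       n = n)
}

#' Injected RNA amount from the UV channel
#'
#' The UV area of a reference canonical nucleoside (guanosine by default in
#' the workflow), corrected for the SIL-IS contribution, divided by the UV
#' response factor gives the pmol of that nucleoside in the sample; division
#' by its residue count in the sequence gives the pmol of injected RNA.
#'
#' @param uv_area_total UV area of the canonical nucleoside in the sample run
#'   (sample + SIL-IS material).
#' @param uv_area_silis UV area contributed by the SIL-IS alone (measured on
#'   a SIL-IS-only run at the same spike level).
#' @param uvf UV response factor, area per pmol (> 0).
#' @param n_residues Count of that canonical residue in the RNA sequence
#'   (>= 1).
#' @return RNA amount in pmol.
#' @export
rna_amount_from_uv <- function(uv_area_total, uv_area_silis, uvf, n_residues) {
  stopifnot(is.numeric(uv_area_total), is.numeric(uv_area_silis),
            uv_area_silis >= 0, uvf > 0, n_residues >= 1)
  if (uv_area_total < uv_area_silis) {
    stop("total UV area below the SIL-IS contribution: ",
         "SIL-IS overspiked or integration fault", call. = FALSE)
  }
  (uv_area_total - uv_area_silis) / (uvf * n_residues)
}

#' Modification yield of a quantified nucleoside
#'
#' Expresses an absolute modified-nucleoside amount relative to the RNA it
#' came from: moles modification per mole RNA (`per_molecule`), the
#' occupancy per presumed site, the percentage of the parent canonical
#' nucleoside, and mol% of all residues when the sequence composition is
#' known.
#'
#' @param mod_pmol Amount of the modified nucleoside (pmol).
#' @param rna_pmol Amount of injected RNA (pmol, > 0).
#' @param sites Number of presumed modification sites (>= 1).
#' @param parent_count Count of the parent canonical nucleoside in the
#'   sequence (required for `pct_of_parent`).
#' @param total_residues Sequence length (required for `mol_pct`).
#' @return List with `per_molecule`, `occupancy`, `pct_of_parent` and
#'   `mol_pct` (the latter two `NA` when the counts are not supplied).
#' @export
modification_yield <- function(mod_pmol, rna_pmol, sites = 1,
                               parent_count = NULL, total_residues = NULL) {
  stopifnot(mod_pmol >= 0, rna_pmol > 0, sites >= 1)
  per_molecule <- mod_pmol / rna_pmol
  list(
    per_molecule = per_molecule,
    occupancy = per_molecule / sites,
    pct_of_parent = if (is.null(parent_count)) NA_real_ else {
      stopifnot(parent_count >= 1)
      100 * mod_pmol / (rna_pmol * parent_count)
    },
    mol_pct = if (is.null(total_residues)) NA_real_ else {
      stopifnot(total_residues >= 1)
      100 * per_molecule / total_residues
    }
  )
}

#' Spike-in recovery check
#'
#' Compares the quantification of an aliquot spiked with a known amount of a
#' nucleoside to the unspiked aliquot. A recovery near 1 verifies the rRFN on
#' the actual sample matrix.
#'
#' @param sample_result,spiked_result `quant_result` objects from
#'   [quantify_sample()] (or their `amounts` tibbles).
#' @param spike_pmol Spiked amount in pmol (> 0).
#' @param nucleoside Nucleoside symbol quantified in both results.
#' @param tolerance Acceptance half-width on `|recovery - 1|` (default 0.05).
#' @return List with `recovery` (fraction of the spike recovered) and logical
#'   `pass`.
#' @export
spike_check <- function(sample_result, spiked_result, spike_pmol, nucleoside,
                        tolerance = 0.05) {
  stopifnot(spike_pmol > 0)
  lookup <- function(res) {
    amounts <- if (inherits(res, "quant_result")) res$amounts else res
    row <- amounts[amounts$nucleoside == nucleoside, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("nucleoside '", nucleoside, "' not quantified in result", call. = FALSE)
    }
    row$pmol
  }
  recovery <- (lookup(spiked_result) - lookup(sample_result)) / spike_pmol
  list(recovery = recovery, pass = abs(recovery - 1) <= tolerance)
}

#' Quantify a measured sample against a response-factor table
#'
#' Applies the full absolute-quantification workflow to one sample run:
#' per modified nucleoside, replicate NIFs are converted to pmol via the
#' rRFN; the injected RNA amount is determined from the SIL-IS-corrected UV
#' area of the reference canonical nucleoside; and modification yields are
#' derived when residue counts are available. Nucleosides present in the
#' measurements but lacking an rRFN (no external calibration) are skipped
#' with a warning naming them.
#'
#' @param measurements Measurement table containing the sample run and,
#'   when RNA amounts are requested, a SIL-IS-only run for UV correction.
#' @param rf An `rf_table` ([build_rf_table()] / [read_rf_table()]).
#' @param counts Optional named residue counts (`C`, `U`, `G`, `A`, `total`),
#'   e.g. from [fasta_residue_counts()]; enables RNA amount and yields.
#' @param registry Nucleoside registry (for parent lookups).
#' @param reference Canonical nucleoside used for the UV-based RNA amount
#'   (default `"G"`, empirically the most stable reference), or `"mean"` for
#'   the average over all four canonicals.
#' @param sites Named vector: presumed modification sites per nucleoside
#'   (default 1 each).
#' @param sample_run,silis_run Prefixes of `run_id` identifying the sample
#'   and the SIL-IS-only runs (defaults `"sample"`, `"silis_blank"`).
#' @return Object of class `quant_result`: list with `amounts` (tibble
#'   `nucleoside`, `pmol`, `se`, `n`, `below_loq`, `above_valid_range`),
#'   `rna_pmol`, `rna_se`, and `yields` (tibble, when counts are given).
#' @export
quantify_sample <- function(measurements, rf, counts = NULL,
                            registry = default_registry(),
                            reference = "G", sites = NULL,
                            sample_run = "sample", silis_run = "silis_blank") {
  mt <- validate_measurements(measurements)
  stopifnot(inherits(rf, "rf_table"))
  is_sample <- startsWith(mt$run_id, sample_run)
  smp <- mt[is_sample, , drop = FALSE]
  if (!any(smp$channel == "MS13")) {
    stop("sample run has no MS13 rows: SIL-IS missing", call. = FALSE)
  }
  analytes <- unique(smp$analyte[smp$channel == "MS12"])
  analytes <- setdiff(analytes, canonical_nucleosides())
  has_rf <- analytes[analytes %in% rf$rf$nucleoside[
    !is.na(rf$rf$rrfn_pmol_inv) & rf$rf$rrfn_pmol_inv > 0]]
  no_rf <- setdiff(analytes, has_rf)
  if (length(no_rf) > 0) {
    warning("no rRFN calibration for: ", paste(no_rf, collapse = ", "),
            "; only relative comparison is possible for these")
  }
  rows <- lapply(has_rf, function(nuc) {
    d <- smp[smp$analyte == nuc, , drop = FALSE]
    d12 <- d[d$channel == "MS12", , drop = FALSE]
    d13 <- d[d$channel == "MS13", , drop = FALSE]
    d13 <- d13[match(d12$replicate, d13$replicate), , drop = FALSE]
    if (anyNA(d13$peak_area)) {
      stop("MS13 rows missing for '", nuc, "' in the sample run", call. = FALSE)
    }
    cal <- rf$rf[rf$rf$nucleoside == nuc, , drop = FALSE]
    res <- absolute_amount(d12$peak_area, d13$peak_area,
                           cal$rrfn_pmol_inv, nucleoside = nuc)
    tibble::tibble(
      nucleoside = nuc, pmol = res$pmol, se = res$se, n = res$n,
      below_loq = !is.na(cal$loq_pmol) && res$pmol < cal$loq_pmol,
      above_valid_range = !is.na(cal$valid_hi_pmol) &&
        res$pmol > cal$valid_hi_pmol
    )
  })
  amounts <- dplyr::bind_rows(rows)

  rna_pmol <- NA_real_
  rna_se <- NA_real_
  yields <- NULL
  if (!is.null(counts)) {
    refs <- if (identical(reference, "mean")) canonical_nucleosides() else reference
    sil <- mt[startsWith(mt$run_id, silis_run), , drop = FALSE]
    if (nrow(sil) == 0) {
      stop("no SIL-IS-only run ('", silis_run,
           "') found for UV correction", call. = FALSE)
    }
    per_ref <- vapply(refs, function(rn) {
      uv_tot <- smp$peak_area[smp$analyte == rn & smp$channel == "UV254"]
      uv_sil <- sil$peak_area[sil$analyte == rn & sil$channel == "UV254"]
      if (length(uv_tot) == 0 || length(uv_sil) == 0) {
        stop("UV rows for reference '", rn, "' missing", call. = FALSE)
      }
      uvf_row <- rf$uvf[rf$uvf$nucleoside == rn, , drop = FALSE]
      if (nrow(uvf_row) != 1) {
        stop("no UVF calibration for reference '", rn, "'", call. = FALSE)
      }
      rna_amount_from_uv(stats::median(uv_tot), stats::median(uv_sil),
                         uvf_row$uvf_area_per_pmol, counts[[rn]])
    }, 0)
    rna_pmol <- mean(per_ref)
    rna_se <- if (length(per_ref) > 1) {
      stats::sd(per_ref) / sqrt(length(per_ref))
    } else NA_real_
    yields <- dplyr::bind_rows(lapply(amounts$nucleoside, function(nuc) {
      spec <- registry[[nuc]]
      parent_count <- if (!is.null(spec) && !is.na(spec$parent)) {
        counts[[spec$parent]]
      } else NULL
      y <- modification_yield(
        amounts$pmol[amounts$nucleoside == nuc], rna_pmol,
        sites = if (!is.null(sites) && nuc %in% names(sites)) sites[[nuc]] else 1,
        parent_count = parent_count,
        total_residues = if ("total" %in% names(counts)) counts[["total"]] else NULL
      )
      tibble::tibble(nucleoside = nuc, per_molecule = y$per_molecule,
                     occupancy = y$occupancy, pct_of_parent = y$pct_of_parent,
                     mol_pct = y$mol_pct)
    }))
  }
  structure(
    list(amounts = amounts, rna_pmol = rna_pmol, rna_se = rna_se,
         yields = yields, reference = reference),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result>\n")
  print(x$amounts)
  if (!is.na(x$rna_pmol)) {
    cat(sprintf("RNA amount: %.4g pmol (UV reference: %s)\n",
                x$rna_pmol, paste(x$reference, collapse = "+")))
  }
  if (!is.null(x$yields)) print(x$yields)
  invisible(x)
}

#' Human-readable calculation trace of a quantification
#'
#' Renders the workflow of a `quant_result` as a logged calculation: the
#' per-nucleoside NIF-to-pmol conversion, the UV-based RNA amount, and the
#' resulting yields.
#'
#' @param qr A `quant_result`.
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is given.
#' @export
quant_report <- function(qr, path = NULL) {
  stopifnot(inherits(qr, "quant_result"))
  lines <- c("Absolute quantification report",
             "==============================", "")
  for (i in seq_len(nrow(qr$amounts))) {
    a <- qr$amounts[i, ]
    lines <- c(lines, sprintf(
      "%-6s NIF / rRFN -> %.5g pmol%s%s", a$nucleoside, a$pmol,
      if (!is.na(a$se)) sprintf(" (se %.2g, n=%d)", a$se, a$n) else "",
      paste0(if (isTRUE(a$below_loq)) " [below LOQ]" else "",
             if (isTRUE(a$above_valid_range)) " [above valid range]" else "")
    ))
  }
  if (!is.na(qr$rna_pmol)) {
    lines <- c(lines, "", sprintf(
      "Injected RNA (UV %s, SIL-IS corrected): %.5g pmol",
      paste(qr$reference, collapse = "+"), qr$rna_pmol))
  }
  if (!is.null(qr$yields)) {
    lines <- c(lines, "", "Modification yields:")
    for (i in seq_len(nrow(qr$yields))) {
      y <- qr$yields[i, ]
      lines <- c(lines, sprintf(
        "%-6s %.4g mol/mol RNA; occupancy %.4g; %s%% of parent; %s mol%%",
        y$nucleoside, y$per_molecule, y$occupancy,
        ifelse(is.na(y$pct_of_parent), "NA", sprintf("%.3g", y$pct_of_parent)),
        ifelse(is.na(y$mol_pct), "NA", sprintf("%.3g", y$mol_pct))))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
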