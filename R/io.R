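# Tabular boundary of the workflow: measurement tables, response-factor
# tables and FASTA residue counts.

.MEASUREMENT_COLS <- c("run_id", "session_id", "analyte", "channel",
                       "peak_area", "level_pmol", "replicate")
.CHANNELS <- c("MS12", "MS13", "UV254")

#' Validate a measurement table
#'
#' Checks schema and invariants of the long-form peak-area table: required
#' columns, known channels, non-negative areas, uniqueness of
#' `(run_id, analyte, channel, replicate)`, and UV rows restricted to the
#' canonical nucleosides.
#'
#' @param mt A data frame.
#' @return The validated table as a tibble (invisibly usable in pipelines).
#' @export
validate_measurements <- function(mt) {
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(mt))
  if (length(missing_cols) > 0) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_channel <- which(!mt$channel %in% .CHANNELS)
  if (length(bad_channel) > 0) {
    stop("unknown channel '", mt$channel[bad_channel[1]], "' at row ",
         bad_channel[1], " (column 'channel')", call. = FALSE)
  }
  neg <- which(is.na(mt$peak_area) | mt$peak_area < 0)
  if (length(neg) > 0) {
    stop("negative or missing peak_area at row ", neg[1],
         " (column 'peak_area')", call. = FALSE)
  }
  key <- paste(mt$run_id, mt$analyte, mt$channel, mt$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicated (run_id, analyte, channel, replicate) at row ", dup[1],
         call. = FALSE)
  }
  bad_uv <- which(mt$channel == "UV254" &
                    !mt$analyte %in% canonical_nucleosides())
  if (length(bad_uv) > 0) {
    stop("UV254 row for non-canonical analyte '", mt$analyte[bad_uv[1]],
         "' at row ", bad_uv[1], call. = FALSE)
  }
  tibble::as_tibble(mt)
}

#' Read a measurement table from CSV
#'
#' @param path CSV file with exactly the measurement-table header
#'   (`run_id, session_id, analyte, channel, peak_area, level_pmol,
#'   replicate`), UTF-8, decimal point.
#' @return Validated measurement tibble.
#' @export
read_measurements <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1))
  char_cols <- intersect(c("run_id", "session_id", "analyte", "channel"),
                         header)
  mt <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(
                          rep("character", length(char_cols)), char_cols))
  validate_measurements(mt)
}

# Format numeric columns at full double precision so that CSV round-trips
# are lossless.
.write_csv_full <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
}

#' Write a measurement table to CSV
#'
#' Numeric values are written at full double precision, so
#' `read_measurements(write_measurements(mt))` reproduces `mt` exactly.
#'
#' @param mt Measurement table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(mt, path) {
  mt <- validate_measurements(mt)
  .write_csv_full(mt, path)
  invisible(path)
}

#' Write a response-factor table
#'
#' Writes the rRFN table as CSV (columns `nucleoside`, `rrfn_pmol_inv`, `r2`,
#' `se`, `valid_lo_pmol`, `valid_hi_pmol`, `session_rsd_pct`, `lod_pmol`,
#' `loq_pmol`) and, when present, the UVF table next to it.
#'
#' @param rf An `rf_table` from [build_rf_table()].
#' @param path Output CSV path for the rRFN table.
#' @param uvf_path Output CSV path for the UVF table; default replaces the
#'   extension of `path` with `_uvf.csv`.
#' @return `path`, invisibly.
#' @export
write_rf_table <- function(rf, path, uvf_path = NULL) {
  stopifnot(inherits(rf, "rf_table"))
  .write_csv_full(rf$rf, path)
  if (!is.null(rf$uvf) && nrow(rf$uvf) > 0) {
    if (is.null(uvf_path)) {
      uvf_path <- sub("\\.csv$", "_uvf.csv", path)
    }
    .write_csv_full(rf$uvf, uvf_path)
  }
  invisible(path)
}

#' Read a response-factor table
#'
#' @param path CSV written by [write_rf_table()].
#' @param uvf_path Optional UVF CSV; defaults to the `_uvf.csv` sibling of
#'   `path` when that file exists.
#' @return An `rf_table` (without calibration models).
#' @export
read_rf_table <- function(path, uvf_path = NULL) {
  numerify <- function(df) {
    for (col in setdiff(names(df), "nucleoside")) {
      df[[col]] <- as.numeric(df[[col]])
    }
    df
  }
  rf <- numerify(tibble::as_tibble(utils::read.csv(path,
                                                   stringsAsFactors = FALSE)))
  if (is.null(uvf_path)) {
    cand <- sub("\\.csv$", "_uvf.csv", path)
    if (file.exists(cand)) uvf_path <- cand
  }
  uvf <- if (!is.null(uvf_path)) {
    numerify(tibble::as_tibble(utils::read.csv(uvf_path,
                                               stringsAsFactors = FALSE)))
  } else {
    tibble::tibble(nucleoside = character(), uvf_area_per_pmol = numeric(),
                   r2 = numeric(), se = numeric())
  }
  structure(list(rf = rf, uvf = uvf, models = NULL), class = "rf_table")
}

#' Residue counts of an RNA (or DNA) sequence from FASTA
#'
#' Reads one sequence record and counts the canonical residues. `T` is
#' normalized to `U`, so DNA-alphabet templates of an RNA are accepted;
#' counting is on the given strand only.
#'
#' @param path FASTA file.
#' @param which Index of the record to use when the file has several.
#' @return Named numeric vector with counts for `C`, `U`, `G`, `A` and
#'   `total` (sequence length).
#' @export
fasta_residue_counts <- function(path, which = 1L) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no sequence records in '", path, "'", call. = FALSE)
  s <- toupper(as.character(seqs[[which]]))
  s <- gsub("T", "U", s, fixed = TRUE)
  chars <- strsplit(s, "")[[1]]
  unknown <- setdiff(unique(chars), c("C", "U", "G", "A"))
  if (length(unknown) > 0) {
    warning("non-canonical residue(s) in sequence: ",
            paste(unknown, collapse = ", "),
            "; counted only toward the total")
  }
  counts <- vapply(c("C", "U", "G", "A"), function(b) sum(chars == b), 0)
  c(counts, total = length(chars))
}
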