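# External calibration: linear dynamic range, LOD/LOQ, NIF, rRFN, UVF and
# cross-session stability.

#' Nucleoside-isotope factor (NIF)
#'
#' Ratio of the 12C analyte MS signal to the co-measured 13C isotopomer
#' signal of the same nucleoside. Because both species co-elute and ionize
#' identically, ion suppression, matrix effects and instrument drift multiply
#' both signals equally and cancel in the ratio.
#'
#' @param signal_12c,signal_13c Peak areas; vectors of equal length.
#' @return Numeric vector of NIF values.
#' @export
compute_nif <- function(signal_12c, signal_13c) {
  stopifnot(is.numeric(signal_12c), is.numeric(signal_13c),
            length(signal_12c) == length(signal_13c))
  if (any(signal_13c <= 0)) {
    stop("non-positive 13C signal: SIL-IS missing from run", call. = FALSE)
  }
  signal_12c / signal_13c
}

# Weighted least squares with 1/x weights; through the origin or with
# intercept. Returns slope, intercept, r2 (centered, weighted), se of slope.
.wls_fit <- function(x, y, through_origin) {
  w <- 1 / x
  # exact fits (noiseless limits) are legitimate here; summary.lm warns on them
  if (through_origin) {
    fit <- stats::lm(y ~ 0 + x, weights = w)
    slope <- unname(stats::coef(fit)[1])
    intercept <- 0
    se <- unname(suppressWarnings(summary(fit))$coefficients[1, 2])
  } else {
    fit <- stats::lm(y ~ x, weights = w)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    se <- unname(suppressWarnings(summary(fit))$coefficients[2, 2])
  }
  yhat <- intercept + slope * x
  ybar <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * (y - yhat)^2) / ss_tot else 0
  list(slope = slope, intercept = intercept, r2 = r2, se = se)
}

# Median response per distinct level.
.aggregate_levels <- function(levels, responses) {
  lev <- sort(unique(levels))
  resp <- vapply(lev, function(l) stats::median(responses[levels == l]), 0)
  list(levels = lev, responses = resp)
}

#' Determine the linear dynamic range of a calibration curve
#'
#' Searches for the longest contiguous run of calibration levels over which a
#' weighted (1/x) least-squares line back-calculates every level accurately:
#' interior levels within `tol_mid`, the two terminal levels within
#' `tol_edge` (standard bioanalytical acceptance). Replicate responses are
#' aggregated by median before the search; ties in window length are broken
#' toward the window with the higher R-squared.
#'
#' @param levels Injected amounts (pmol); replicates allowed. Blanks
#'   (level 0) are ignored.
#' @param responses Signals (same length as `levels`).
#' @param tol_mid Relative back-calculation tolerance for interior levels.
#' @param tol_edge Tolerance for the two terminal levels of the window.
#' @param through_origin Force the line through the origin (used for the NIF
#'   channel, where a zero amount gives a zero ratio by construction).
#' @param nucleoside,channel Labels carried into the result.
#' @return A one-row tibble (`calibration model`): `nucleoside`, `channel`,
#'   `slope`, `intercept`, `r2`, `linear_lo`, `linear_hi`, `decades`,
#'   `n_levels`, plus `lod`/`loq` columns initialized to `NA`.
#' @export
fit_linear_range <- function(levels, responses, tol_mid = 0.15,
                             tol_edge = 0.20, through_origin = FALSE,
                             nucleoside = NA_character_,
                             channel = NA_character_) {
  stopifnot(length(levels) == length(responses), all(levels >= 0))
  keep <- levels > 0
  agg <- .aggregate_levels(levels[keep], responses[keep])
  x_all <- agg$levels
  y_all <- agg$responses
  if (length(x_all) < 5) {
    stop("need at least 5 distinct positive levels", call. = FALSE)
  }
  n <- length(x_all)
  best <- NULL
  best_fail <- NULL
  for (i in seq_len(n - 3)) {
    for (j in seq(i + 3, n)) {
      x <- x_all[i:j]
      y <- y_all[i:j]
      fit <- .wls_fit(x, y, through_origin)
      if (!is.finite(fit$slope) || fit$slope <= 0) next
      back <- (y - fit$intercept) / fit$slope
      rel <- abs(back / x - 1)
      tol <- ifelse(seq_along(x) %in% c(1L, length(x)), tol_edge, tol_mid)
      ok <- all(rel <= tol)
      cand <- list(i = i, j = j, n_levels = j - i + 1L, fit = fit,
                   lo = x_all[i], hi = x_all[j], max_rel = max(rel))
      if (ok) {
        if (is.null(best) || cand$n_levels > best$n_levels ||
            (cand$n_levels == best$n_levels && fit$r2 > best$fit$r2)) {
          best <- cand
        }
      } else if (is.null(best_fail) || cand$max_rel < best_fail$max_rel) {
        best_fail <- cand
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0("no linear window of >= 4 levels within tolerance; ",
                        "best candidate %g-%g pmol had max back-calculation ",
                        "error %.1f%%"),
                 best_fail$lo, best_fail$hi, 100 * best_fail$max_rel),
         call. = FALSE)
  }
  tibble::tibble(
    nucleoside = nucleoside, channel = channel,
    slope = best$fit$slope, intercept = best$fit$intercept, r2 = best$fit$r2,
    linear_lo = best$lo, linear_hi = best$hi,
    decades = log10(best$hi / best$lo), n_levels = best$n_levels,
    lod = NA_real_, loq = NA_real_
  )
}

#' Limits of detection and quantification from blank injections
#'
#' The 3-sigma / 10-sigma convention: `LOD = 3 sd(blanks) / slope`,
#' `LOQ = 10 sd(blanks) / slope`, in pmol.
#'
#' @param blank_signals Peak areas of blank injections (>= 3 values).
#' @param slope Calibration slope, signal per pmol (> 0).
#' @return Named numeric vector `c(lod = , loq = )`; `(0, 0)` with a warning
#'   when the blanks have zero variance.
#' @export
estimate_lod_loq <- function(blank_signals, slope) {
  stopifnot(length(blank_signals) >= 3, is.numeric(slope), slope > 0)
  s <- stats::sd(blank_signals)
  if (s == 0) {
    warning("blank signals have zero variance; LOD/LOQ reported as 0")
    return(c(lod = 0, loq = 0))
  }
  c(lod = 3 * s / slope, loq = 10 * s / slope)
}

#' Fit the relative response factor (rRFN) of a nucleoside
#'
#' Weighted (1/x) least squares of NIF versus injected amount, through the
#' origin (a zero amount yields a zero isotopomer ratio by construction). The
#' slope is the rRFN in 1/pmol: it converts a measured NIF directly into an
#' absolute amount.
#'
#' @param amounts Injected 12C amounts (pmol), within the NIF linear window;
#'   at least 5 points.
#' @param nifs NIF values (non-negative), same length.
#' @return List with `rrfn`, `r2`, `se` and logical `flag_degenerate` (set
#'   when all NIFs are zero, in which case `rrfn = 0` and `r2 = 0`).
#' @export
fit_rrfn <- function(amounts, nifs) {
  stopifnot(length(amounts) == length(nifs), length(amounts) >= 5,
            all(amounts > 0))
  if (any(nifs < 0)) stop("negative NIF values", call. = FALSE)
  if (all(nifs == 0)) {
    return(list(rrfn = 0, r2 = 0, se = 0, flag_degenerate = TRUE))
  }
  fit <- .wls_fit(amounts, nifs, through_origin = TRUE)
  # NIF scatter is proportional to the amount itself, so the model-based WLS
  # error would be optimistic. When replicate injections are present
  # (repeated amounts), pool their relative scatter into one noise CV and
  # propagate it to the slope; otherwise fall back to a leverage-corrected
  # (HC3-style) sandwich error.
  w <- 1 / amounts
  denom <- sum(w * amounts^2)
  cv2 <- NA_real_
  if (anyDuplicated(amounts)) {
    grp <- split(nifs, amounts)
    num <- df <- 0
    for (g in grp) {
      mg <- mean(g)
      if (length(g) >= 2 && mg > 0) {
        num <- num + sum((g - mg)^2) / mg^2
        df <- df + length(g) - 1
      }
    }
    if (df >= 4) cv2 <- num / df
  }
  if (is.finite(cv2)) {
    se <- sqrt(cv2 * fit$slope^2 * sum((w * amounts^2)^2)) / denom
  } else {
    resid <- nifs - fit$slope * amounts
    lev <- w * amounts^2 / denom
    se <- sqrt(sum((w * amounts * resid / (1 - lev))^2)) / denom
  }
  list(rrfn = fit$slope, r2 = fit$r2, se = se, flag_degenerate = FALSE)
}

#' Fit the UV response factor (UVF) of a canonical nucleoside
#'
#' Ordinary least squares of UV area versus amount through the origin
#' (1/x weighted). The UVF (area per pmol) is the operational form of the
#' extinction coefficient at 254 nm and is defined only for the four
#' canonical nucleosides.
#'
#' @param amounts Injected amounts (pmol), positive.
#' @param uv_areas UV peak areas.
#' @param nucleoside Canonical nucleoside symbol (`"C"`, `"U"`, `"G"`, `"A"`).
#' @return List with `uvf`, `r2`, `se`.
#' @export
fit_uvf <- function(amounts, uv_areas, nucleoside) {
  if (!nucleoside %in% canonical_nucleosides()) {
    stop("UVF is defined only for canonical nucleosides (C, U, G, A), not '",
         nucleoside, "'", call. = FALSE)
  }
  stopifnot(length(amounts) == length(uv_areas), all(amounts > 0))
  fit <- .wls_fit(amounts, uv_areas, through_origin = TRUE)
  list(uvf = fit$slope, r2 = fit$r2, se = fit$se)
}

#' Cross-session stability of a response factor
#'
#' Relative standard deviation (percent) of per-session estimates:
#' `100 * sd / mean`, with the sample (n-1) standard deviation.
#'
#' @param values Per-session estimates (>= 2), e.g. rRFN values.
#' @return RSD in percent.
#' @export
session_stability <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 sessions", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of session values is zero; RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

# Replicate-level blank-corrected NIFs of one analyte: one row per
# (session, level, replicate).
.replicate_nifs <- function(mt, analyte, blank_correct = TRUE) {
  ms <- mt[mt$analyte == analyte & mt$channel %in% c("MS12", "MS13") &
             !is.na(mt$level_pmol), , drop = FALSE]
  out <- lapply(split(ms, ms$session_id), function(d) {
    b <- if (blank_correct && any(d$level_pmol == 0)) {
      stats::median(d$peak_area[d$level_pmol == 0 & d$channel == "MS12"])
    } else 0
    d12 <- d[d$channel == "MS12" & d$level_pmol > 0, , drop = FALSE]
    d13 <- d[d$channel == "MS13" & d$level_pmol > 0, , drop = FALSE]
    key <- paste(d13$level_pmol, d13$replicate)
    m <- match(paste(d12$level_pmol, d12$replicate), key)
    tibble::tibble(
      session_id = d12$session_id,
      level_pmol = d12$level_pmol,
      replicate = d12$replicate,
      nif = compute_nif(pmax(d12$peak_area - b, 0),
                        pmax(d13$peak_area[m] - b, 1e-12))
    )
  })
  dplyr::bind_rows(out)
}

# Per-(session, level) median signals of one analyte, with optional blank
# correction of the MS channels (median blank area subtracted, floored at 0).
.level_medians <- function(mt, analyte, blank_correct = TRUE) {
  ms <- mt[mt$analyte == analyte & mt$channel %in% c("MS12", "MS13") &
             !is.na(mt$level_pmol), , drop = FALSE]
  if (nrow(ms) == 0) return(NULL)
  out <- lapply(split(ms, ms$session_id), function(d) {
    lev <- sort(unique(d$level_pmol))
    m12 <- vapply(lev, function(l)
      stats::median(d$peak_area[d$level_pmol == l & d$channel == "MS12"]), 0)
    m13 <- vapply(lev, function(l)
      stats::median(d$peak_area[d$level_pmol == l & d$channel == "MS13"]), 0)
    # The 12C blank measures the additive baseline; the 13C channel at the
    # blank level still carries the SIL-IS spike, so the same baseline
    # estimate is subtracted from both channels.
    b <- if (blank_correct && 0 %in% lev) m12[lev == 0] else 0
    tibble::tibble(
      session_id = d$session_id[1], level_pmol = lev,
      ms12 = pmax(m12 - b, 0), ms13 = pmax(m13 - b, 0),
      ms12_raw = m12, ms13_raw = m13
    )
  })
  dplyr::bind_rows(out)
}

#' Build the response-factor table from a calibration measurement table
#'
#' The full calibration workflow. Per nucleoside with both MS channels:
#' aggregate replicates by median per level (with blank correction of the MS
#' signals), determine the raw 12C linear window and the NIF linear window,
#' estimate LOD/LOQ from the blank injections and the raw slope, fit the rRFN
#' per session inside the NIF window, and summarize the cross-session RSD.
#' Per canonical nucleoside, fit the UVF from the UV channel.
#'
#' @param measurements A calibration measurement table (see
#'   [simulate_calibration()] / [read_measurements()]), with `level_pmol` set
#'   and blanks at level 0.
#' @param tol_mid,tol_edge Back-calculation tolerances for the window search.
#' @param blank_correct Subtract the per-session median blank area from the
#'   MS signals before forming NIFs and fitting.
#' @return Object of class `rf_table`: list with
#'   \describe{
#'     \item{rf}{tibble `nucleoside`, `rrfn_pmol_inv`, `r2`, `se`,
#'       `valid_lo_pmol`, `valid_hi_pmol`, `session_rsd_pct`, `lod_pmol`,
#'       `loq_pmol`.}
#'     \item{uvf}{tibble `nucleoside`, `uvf_area_per_pmol`, `r2`, `se`.}
#'     \item{models}{tibble of per-channel calibration models (session 1).}
#'   }
#' @export
build_rf_table <- function(measurements, tol_mid = 0.15, tol_edge = 0.20,
                           blank_correct = TRUE) {
  mt <- validate_measurements(measurements)
  analytes <- unique(mt$analyte[mt$channel == "MS12"])
  rf_rows <- list()
  model_rows <- list()
  for (nuc in analytes) {
    med <- .level_medians(mt, nuc, blank_correct = blank_correct)
    if (is.null(med)) next
    sessions <- unique(med$session_id)
    s1 <- med[med$session_id == sessions[1] & med$level_pmol > 0, , drop = FALSE]
    raw_model <- fit_linear_range(s1$level_pmol, s1$ms12, tol_mid, tol_edge,
                                  through_origin = FALSE, nucleoside = nuc,
                                  channel = "MS12")
    nif1 <- compute_nif(s1$ms12, s1$ms13)
    nif_model <- fit_linear_range(s1$level_pmol, nif1, tol_mid, tol_edge,
                                  through_origin = TRUE, nucleoside = nuc,
                                  channel = "NIF")
    blanks <- mt$peak_area[mt$analyte == nuc & mt$channel == "MS12" &
                             !is.na(mt$level_pmol) & mt$level_pmol == 0]
    lodloq <- if (length(blanks) >= 3) {
      estimate_lod_loq(blanks, raw_model$slope)
    } else c(lod = NA_real_, loq = NA_real_)
    raw_model$lod <- lodloq[["lod"]]
    raw_model$loq <- lodloq[["loq"]]
    # per-session rRFN inside the NIF linear window of session 1, fitted on
    # replicate-level NIFs (the window search itself used level medians)
    rnifs <- .replicate_nifs(mt, nuc, blank_correct = blank_correct)
    rnifs <- rnifs[rnifs$level_pmol >= nif_model$linear_lo &
                     rnifs$level_pmol <= nif_model$linear_hi, , drop = FALSE]
    rrfn_by_session <- vapply(sessions, function(s) {
      d <- rnifs[rnifs$session_id == s, , drop = FALSE]
      fit_rrfn(d$level_pmol, d$nif)$rrfn
    }, 0)
    rrfn_fit <- fit_rrfn(rnifs$level_pmol, rnifs$nif)
    rf_rows[[nuc]] <- tibble::tibble(
      nucleoside = nuc,
      rrfn_pmol_inv = rrfn_fit$rrfn,
      r2 = rrfn_fit$r2,
      se = rrfn_fit$se,
      valid_lo_pmol = nif_model$linear_lo,
      valid_hi_pmol = nif_model$linear_hi,
      session_rsd_pct = if (length(sessions) >= 2) {
        session_stability(rrfn_by_session)
      } else NA_real_,
      lod_pmol = raw_model$lod,
      loq_pmol = raw_model$loq
    )
    model_rows[[paste0(nuc, "-raw")]] <- raw_model
    model_rows[[paste0(nuc, "-nif")]] <- nif_model
  }
  uvf_rows <- list()
  for (nuc in intersect(unique(mt$analyte[mt$channel == "UV254"]),
                        canonical_nucleosides())) {
    uv <- mt[mt$analyte == nuc & mt$channel == "UV254" &
               !is.na(mt$level_pmol) & mt$level_pmol > 0, , drop = FALSE]
    fit <- fit_uvf(uv$level_pmol, uv$peak_area, nuc)
    uvf_rows[[nuc]] <- tibble::tibble(
      nucleoside = nuc, uvf_area_per_pmol = fit$uvf, r2 = fit$r2, se = fit$se
    )
  }
  structure(
    list(rf = dplyr::bind_rows(rf_rows), uvf = dplyr::bind_rows(uvf_rows),
         models = dplyr::bind_rows(model_rows)),
    class = "rf_table"
  )
}

#' Full-range NIF linearity fit
#'
#' Fits the weighted through-origin NIF-versus-amount line over the entire
#' calibration grid of one nucleoside -- including levels deep inside the MS
#' saturation zone -- excluding only levels below the LOQ of the raw 12C
#' channel. Because suppression affects both isotopomers equally, this fit
#' stays linear where the raw calibration curve has long flattened; its
#' R-squared measures how completely the isotopomer ratio cancels saturation.
#'
#' @param measurements Calibration measurement table (single session, or the
#'   first session is used).
#' @param nucleoside Nucleoside symbol.
#' @param blank_correct See [build_rf_table()].
#' @return List with `levels`, `nifs` (per-level medians used), `rrfn`, `r2`,
#'   `se` and `loq` (the 12C-channel LOQ applied as lower cutoff).
#' @export
nif_full_range_fit <- function(measurements, nucleoside, blank_correct = TRUE) {
  mt <- validate_measurements(measurements)
  med <- .level_medians(mt, nucleoside, blank_correct = blank_correct)
  if (is.null(med)) stop("no MS rows for '", nucleoside, "'", call. = FALSE)
  s1 <- med[med$session_id == med$session_id[1] & med$level_pmol > 0, ,
            drop = FALSE]
  raw <- fit_linear_range(s1$level_pmol, s1$ms12, through_origin = FALSE,
                          nucleoside = nucleoside, channel = "MS12")
  blanks <- mt$peak_area[mt$analyte == nucleoside & mt$channel == "MS12" &
                           !is.na(mt$level_pmol) & mt$level_pmol == 0]
  loq <- if (length(blanks) >= 3) {
    estimate_lod_loq(blanks, raw$slope)[["loq"]]
  } else 0
  keep <- s1$level_pmol >= loq
  fit <- fit_rrfn(s1$level_pmol[keep], compute_nif(s1$ms12[keep], s1$ms13[keep]))
  list(levels = s1$level_pmol[keep],
       nifs = compute_nif(s1$ms12[keep], s1$ms13[keep]),
       rrfn = fit$rrfn, r2 = fit$r2, se = fit$se, loq = loq)
}

#' @export
print.rf_table <- function(x, ...) {
  cat(sprintf("<rf_table> rRFN for %d nucleoside(s); UVF for %d canonical(s)\n",
              nrow(x$rf), nrow(x$uvf)))
  print(x$rf)
  invisible(x)
}
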