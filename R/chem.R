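# Nucleoside registry, isotopologue math and MRM transition derivation.

# Monoisotopic atomic masses (Da). Low-resolution instrument comparisons are
# made at one decimal, but all arithmetic is done at full precision.
.ATOMIC_MASS <- c(
  C = 12.000000, H = 1.007825, N = 14.003074, O = 15.994915,
  S = 31.972071, P = 30.973762
)
.MASS_13C <- 13.003355
.MASS_PROTON <- 1.007276

# Neutral losses for the glycosidic-bond fragmentation monitored in MRM.
.LOSS_RIBOSE <- 132.0423        # C5H8O4
.LOSS_METHYLRIBOSE <- 146.0579  # C6H10O4

#' Natural abundance of carbon-13
#'
#' Default per-atom probability of 13C in unlabeled material (1.1 %).
#' @export
NATURAL_13C <- 0.011

#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as `"C11H15N5O4"` into a named integer
#' vector of element counts.
#'
#' @param formula Character scalar, e.g. `"C10H13N5O4"`.
#' @return Named integer vector (element -> count).
#' @examples
#' parse_formula("C11H15N5O4")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  bad <- setdiff(el, names(.ATOMIC_MASS))
  if (length(bad) > 0) {
    stop("unknown element symbol(s) in formula '", formula, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Construct a nucleoside specification
#'
#' A `nucleoside_spec` bundles the chemistry and MRM identity of one
#' (canonical or modified) ribonucleoside: elemental formula, carbon count,
#' parent canonical nucleoside, sugar type (which determines the neutral loss
#' of the MRM transition), and an optional explicit transition for species
#' such as pseudouridine whose C-glycosidic bond does not fragment by ribose
#' loss.
#'
#' @param short_name Symbol, e.g. `"Am"`; unique within a registry.
#' @param formula Elemental formula string, e.g. `"C11H15N5O4"`.
#' @param full_name Long name (optional).
#' @param parent Parent canonical nucleoside, one of `"C","U","G","A"`, or
#'   `NA` for canonicals.
#' @param canonical Logical; is this one of the four major nucleosides?
#' @param sugar One of `"ribose"`, `"methylribose"` (2'-O-methylated) or
#'   `"none"` (C-glycosides; requires `transition_override`).
#' @param transition_override Optional numeric length-2 vector
#'   `(precursor m/z, product m/z)` returned verbatim by [mrm_transition()].
#' @param rt_window Optional retention-time window in minutes, length 2.
#' @param no_external_calibration Logical; `TRUE` for nucleosides detectable
#'   in digests but not available as weighable pure substance, so that no
#'   external calibration (and hence no rRFN) is possible.
#' @return Object of class `nucleoside_spec`.
#' @export
nucleoside_spec <- function(short_name, formula, full_name = short_name,
                            parent = NA_character_, canonical = FALSE,
                            sugar = c("ribose", "methylribose", "none"),
                            transition_override = NULL, rt_window = NULL,
                            no_external_calibration = FALSE) {
  sugar <- match.arg(sugar)
  comp <- parse_formula(formula)
  if (!"H" %in% names(comp)) {
    stop("formula of '", short_name, "' contains no hydrogen; cannot be protonated",
         call. = FALSE)
  }
  if (!is.null(transition_override)) {
    stopifnot(is.numeric(transition_override), length(transition_override) == 2L,
              all(transition_override > 0))
  }
  if (!is.null(rt_window)) {
    stopifnot(is.numeric(rt_window), length(rt_window) == 2L,
              rt_window[1] < rt_window[2])
  }
  structure(
    list(
      short_name = as.character(short_name),
      full_name = as.character(full_name),
      formula = comp,
      formula_string = formula,
      n_carbon = unname(comp["C"] %||% 0L),
      parent = as.character(parent),
      canonical = isTRUE(canonical),
      sugar = sugar,
      transition_override = transition_override,
      rt_window = rt_window,
      no_external_calibration = isTRUE(no_external_calibration)
    ),
    class = "nucleoside_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' @export
print.nucleoside_spec <- function(x, ...) {
  cat(sprintf("<nucleoside_spec> %s (%s), %s, %d C, parent %s, sugar %s\n",
              x$short_name, x$full_name, x$formula_string, x$n_carbon,
              ifelse(is.na(x$parent), "-", x$parent), x$sugar))
  invisible(x)
}

#' Read a nucleoside registry from JSON
#'
#' The registry file is a JSON array with one object per nucleoside carrying
#' `short_name`, `formula`, optional `full_name`, `parent`, `canonical`,
#' `sugar`, `transition` (length-2 m/z pair), `rt_window` and
#' `no_external_calibration` fields.
#'
#' @param path Path to the JSON registry file.
#' @return A `nucleoside_registry`: named list of [nucleoside_spec()] objects.
#' @export
read_registry <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(entries, function(e) {
    nucleoside_spec(
      short_name = e$short_name,
      formula = e$formula,
      full_name = e$full_name %||% e$short_name,
      parent = e$parent %||% NA_character_,
      canonical = isTRUE(e$canonical),
      sugar = e$sugar %||% "ribose",
      transition_override = if (!is.null(e$transition)) unlist(e$transition),
      rt_window = if (!is.null(e$rt_window)) unlist(e$rt_window),
      no_external_calibration = isTRUE(e$no_external_calibration)
    )
  })
  nm <- vapply(specs, `[[`, "", "short_name")
  if (anyDuplicated(nm)) {
    stop("duplicate short_name in registry: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(specs) <- nm
  structure(specs, class = "nucleoside_registry")
}

#' Default nucleoside registry
#'
#' The registry shipped with the package: the four canonical ribonucleosides,
#' the modified nucleosides available as weighable substance for external
#' calibration, and the detectable-but-not-calibratable species (D, m3C,
#' m2A, m1G, m2G), flagged `no_external_calibration`.
#'
#' @return A `nucleoside_registry`.
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "nucleosides.json", package = "silis"))
}

#' @export
print.nucleoside_registry <- function(x, ...) {
  cat(sprintf("<nucleoside_registry> %d nucleosides: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Look up a nucleoside in a registry
#' @param registry A `nucleoside_registry`.
#' @param short_name Nucleoside symbol.
#' @return A `nucleoside_spec`.
#' @export
get_spec <- function(registry, short_name) {
  spec <- registry[[short_name]]
  if (is.null(spec)) {
    stop("unknown nucleoside '", short_name, "'; registry has: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  spec
}

#' Monoisotopic m/z of the protonated nucleoside
#'
#' Computes the `[M+H]+` m/z of a nucleoside, either with natural (all-12C
#' monoisotopic) carbon or uniformly 13C-labeled carbon. The labeled minus
#' unlabeled difference equals `n_carbon * (m(13C) - m(12C))`, i.e. close to
#' one mass unit per carbon atom, which is how the biosynthetic internal
#' standard separates from the analyte in the mass domain.
#'
#' @param spec A [nucleoside_spec()].
#' @param uniform_13c Logical; if `TRUE` every carbon uses the 13C mass.
#' @return The protonated monoisotopic m/z (single charge).
#' @examples
#' reg <- default_registry()
#' protonated_mz(get_spec(reg, "Am"))                       # ~282.1
#' protonated_mz(get_spec(reg, "Am"), uniform_13c = TRUE)   # ~293.2
#' @export
protonated_mz <- function(spec, uniform_13c = FALSE) {
  stopifnot(inherits(spec, "nucleoside_spec"))
  comp <- spec$formula
  masses <- .ATOMIC_MASS[names(comp)]
  if (uniform_13c && "C" %in% names(comp)) masses["C"] <- .MASS_13C
  sum(masses * comp) + .MASS_PROTON
}

#' MRM transition of a nucleoside
#'
#' Derives the (precursor, product) m/z pair monitored in multiple reaction
#' monitoring. For ordinary N-glycosides the product ion is the protonated
#' nucleobase after neutral loss of the ribose (132.0423 Da); for
#' 2'-O-methylated nucleosides the methylribose (146.0579 Da) is lost
#' instead. C-glycosides such as pseudouridine do not fragment this way and
#' must carry an explicit `transition_override`, which is returned verbatim.
#'
#' @param spec A [nucleoside_spec()].
#' @return Named numeric vector `c(precursor_mz = , product_mz = )`.
#' @examples
#' mrm_transition(get_spec(default_registry(), "A"))  # 268.1 -> 136.1
#' @export
mrm_transition <- function(spec) {
  stopifnot(inherits(spec, "nucleoside_spec"))
  if (!is.null(spec$transition_override)) {
    return(c(precursor_mz = spec$transition_override[1],
             product_mz = spec$transition_override[2]))
  }
  if (spec$sugar == "none") {
    stop("transition for '", spec$short_name,
         "' cannot be derived from a glycosidic neutral loss; ",
         "supply transition_override", call. = FALSE)
  }
  prec <- protonated_mz(spec)
  loss <- switch(spec$sugar, ribose = .LOSS_RIBOSE,
                 methylribose = .LOSS_METHYLRIBOSE)
  c(precursor_mz = prec, product_mz = prec - loss)
}

#' Carbon isotopologue pattern of a nucleoside
#'
#' Models the relative abundances of the carbon isotopologues of a nucleoside
#' at a given per-atom 13C probability `p13`. Each of the `n_carbon` carbon
#' positions is 13C independently with probability `p13`, so the intensity at
#' integer mass offset `k` (k atoms of 13C) is the binomial probability
#' `Binomial(n_carbon, p13)` at `k`. With natural material `p13` is ~0.011;
#' for the biosynthetic internal standard it is the labeling efficiency
#' (~0.99).
#'
#' @param spec A [nucleoside_spec()].
#' @param p13 Per-atom probability that a carbon is 13C, in `[0, 1]`.
#' @return Object of class `isotopologue_pattern`: list with `base_mz` (the
#'   all-12C protonated m/z), `intensities` (named numeric vector over mass
#'   offsets `0..n_carbon`, summing to 1) and `p13`.
#' @examples
#' pat <- isotopologue_pattern(get_spec(default_registry(), "Am"), 0.011)
#' pat$intensities[["1"]] / pat$intensities[["0"]]  # the M+1 isotope peak
#' @export
isotopologue_pattern <- function(spec, p13 = NATURAL_13C) {
  stopifnot(inherits(spec, "nucleoside_spec"),
            is.numeric(p13), length(p13) == 1L, p13 >= 0, p13 <= 1)
  n <- spec$n_carbon
  k <- 0:n
  intens <- stats::dbinom(k, size = n, prob = p13)
  intens <- intens / sum(intens)
  names(intens) <- as.character(k)
  structure(
    list(base_mz = protonated_mz(spec), intensities = intens, p13 = p13,
         n_carbon = n),
    class = "isotopologue_pattern"
  )
}

#' Estimate 13C labeling efficiency from the leading isotopologue ratio
#'
#' For highly labeled material the two strongest isotopologues are the fully
#' labeled species (mass offset `n`) and the one-residual-12C species (offset
#' `n - 1`). Their binomial intensity ratio is
#' `I(n-1)/I(n) = n (1 - p)/p`, so the per-atom labeling efficiency is
#' recovered as `p = n / (n + ratio)`. This inverts
#' [isotopologue_pattern()] exactly for any `p13` in `(0, 1]`.
#'
#' @param ratio_Mminus1_to_M Observed intensity ratio of the `M-1`
#'   isotopologue to the fully labeled `M` peak (non-negative).
#' @param n_carbon Number of carbon atoms (>= 1).
#' @return Estimated per-atom 13C probability.
#' @examples
#' estimate_labeling_efficiency(1/9, 11)  # 0.99
#' @export
estimate_labeling_efficiency <- function(ratio_Mminus1_to_M, n_carbon) {
  stopifnot(is.numeric(ratio_Mminus1_to_M), ratio_Mminus1_to_M >= 0,
            is.numeric(n_carbon), n_carbon >= 1)
  n_carbon / (n_carbon + ratio_Mminus1_to_M)
}

#' Export the dMRM transition list of a registry
#'
#' Builds a dynamic-MRM style method table (one transition per nucleoside,
#' with retention-time windows) and optionally writes it as CSV.
#'
#' @param registry A `nucleoside_registry`.
#' @param path Optional path; when given, the table is written as CSV.
#' @return A tibble with columns `name`, `precursor_mz`, `product_mz`,
#'   `rt_window_start`, `rt_window_end`.
#' @export
transition_list <- function(registry, path = NULL) {
  rows <- lapply(registry, function(spec) {
    tr <- mrm_transition(spec)
    tibble::tibble(
      name = spec$short_name,
      precursor_mz = unname(tr["precursor_mz"]),
      product_mz = unname(tr["product_mz"]),
      rt_window_start = if (is.null(spec$rt_window)) NA_real_ else spec$rt_window[1],
      rt_window_end = if (is.null(spec$rt_window)) NA_real_ else spec$rt_window[2]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Canonical nucleoside symbols
#' @return Character vector `c("C", "U", "G", "A")`.
#' @export
canonical_nucleosides <- function() c("C", "U", "G", "A")
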