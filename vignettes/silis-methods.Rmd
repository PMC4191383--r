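---
title: "Quantifying RNA modifications with a biosynthetic 13C internal standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA modifications with a biosynthetic 13C internal standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silis)
```

## The measurement problem

LC–MS/MS is the method of choice for quantifying modified ribonucleosides:
after enzymatic digestion of an RNA sample to nucleosides, each species is
monitored by a multiple-reaction-monitoring (MRM) transition — typically the
protonated nucleoside losing its ribose (132.04 Da) or, for 2′-O-methylated
species, its methylribose (146.06 Da). Sensitivity reaches the low-femtomole
range, but the MS response factor of a nucleoside is *not* a stable property:
it depends on instrument state (which drifts over weeks), on co-eluting
matrix (ion suppression), and on the analyte's ionization chemistry. A raw
peak area is therefore hard to convert into an amount of substance, and the
calibration curve saturates in the 1–10 pmol range.

The workflow implemented here stabilizes the response factor with a
*biosynthetic stable-isotope-labeled internal standard* (SIL-IS): a digest of
total RNA from bacteria grown on uniformly `^13^C`-labeled glucose. Every
detectable modification is present in the standard as a `^13^C` isotopomer
that co-elutes with, and ionizes identically to, its unlabeled counterpart.
The `chem` layer of the package models the consequences: an `n`-carbon
nucleoside shifts by `n` mass units (e.g. +11 for 2′-O-methyladenosine), and
the carbon isotopologue distribution at per-atom `^13^C` probability $p$ is
$\mathrm{Binomial}(n, p)$, so the labeling efficiency is recovered from the
observed $M\!-\!1$/$M$ intensity ratio $r$ as $p = n/(n + r)$.

## NIF, rRFN and Equation-style quantification

For each nucleoside the instrument records the unlabeled analyte signal
$S_{12}$ and the isotopomer signal $S_{13}$ in the same run. Their ratio

$$\mathrm{NIF} = \frac{S_{12}}{S_{13}}$$

(the *nucleoside-isotope factor*) is invariant to any effect that multiplies
both channels equally: ion suppression, source drift, injection losses. A
dilution series of weighed analyte at a constant SIL-IS spike yields a NIF
that is proportional to the injected amount far beyond the saturation of the
raw signal; the slope of the weighted through-origin fit is the *relative
response factor*

$$\mathrm{rRFN} = \frac{\mathrm{NIF}}{\text{amount (pmol)}},$$

and an unknown sample is quantified as
$\text{pmol} = S_{12} / (\mathrm{rRFN}\cdot S_{13})$
(`absolute_amount()`). Because the SIL-IS amount itself sets the
denominator, the true rRFN in the simulator equals the reciprocal of the
spike amount — the parameter-recovery invariant the test suite asserts.

Modification yields relate that amount to the injected RNA, which is
determined from the UV trace at 254 nm: the UV response is linear over a far
wider range than MS, and the UV response factor (UVF, area/pmol) is the
operational form of the extinction coefficient. The area of a reference
canonical nucleoside (guanosine by default — an empirical recommendation;
the reference, or the mean of all four canonicals, is configurable since no
mechanism singles out G) is corrected for the SIL-IS contribution using a
measured SIL-IS-only run, and divided by UVF times the residue count:
`rna_amount_from_uv()`. Yields follow as mol modification per mol RNA, per
site (occupancy), % of parent nucleoside, or mol% of all residues.

Relative comparison of two samples needs no calibration at all: each
modified-nucleoside signal is divided by its isotopomer signal and then by
the UV sum of the four canonicals (`normalized_level()`), and the ratio of
levels is the fold change. Absolute quantification still earns its keep
there: a fold change formed from two trace-level signals is noise, so
nucleosides below a per-molecule threshold (default 0.01 mol/mol RNA,
configurable — "present in traces" is not otherwise quantified) in *all*
samples are flagged as background (`flag_background()`).

## What the simulator emulates

`instrument_model()` + `simulate_calibration()` / `simulate_digest()`
generate the measurement tables the analysis consumes. The signal model is:

* **Shared saturation.** Mean signals are
  $rf \cdot a \cdot \varphi$ with
  $\varphi = 1/(1 + (a_{12}+a_{13})/k_\mathrm{sat})$ applied to both
  isotopomer channels. The hyperbola is the simplest shared-suppression form
  that reproduces both a multi-decade raw linear window and exact NIF
  cancellation; the "true" saturation shape is unknown and only its shared
  action on co-eluting isotopomers matters for the method. Default
  $k_\mathrm{sat} = 5$ pmol places saturation onset in the 1–10 pmol region.
* **Session drift.** One lognormal factor per session and nucleoside
  (mean 1, CV `drift_cv`, default 0.24) multiplies `rf` in both MS channels.
  Near-total sharing between channels is the mechanism that lets a 24% raw
  fluctuation collapse to sub-2% rRFN variation.
* **Per-injection noise.** Independent per channel: multiplicative
  $(1+\mathcal N(0, 0.01))$, giving a NIF CV of about 1.4% per injection,
  plus a strictly positive lognormal additive background with mean and sd
  `sigma_add` (default 3 counts). A Gaussian additive term would produce
  negative blank areas, which integrated peak tables never contain; the
  lognormal keeps the blank standard deviation equal to `sigma_add`, the
  quantity the 3σ/10σ LOD/LOQ rule consumes.
* **Response scale.** `rf` defaults to $10^6$ counts/pmol so that with
  `sigma_add = 3` the LOD/LOQ land in the amol–fmol regime typical of
  triple-quadrupole MRM, and the raw linear window spans four decades.
* **UV channel.** Linear in amount with 0.5% multiplicative noise and no
  drift — UV detection is the stable reference of the workflow. Calibration
  UV rows model the SIL-IS-free calibration set; digest UV rows include the
  SIL-IS material (default 70 pmol per canonical, the scale of a 100 ng
  total-RNA digest), which is why a SIL-IS-only blank run accompanies every
  simulated digest.
* **Calibration grid.** Fifteen half-decade levels from 0.01 fmol to
  100 pmol plus a blank, with 3 replicate injections per level; the SIL-IS
  spike is 0.1 pmol per nucleoside.

The simulator does *not* emulate chromatography (peak shapes, retention-time
drift, carryover), natural-abundance cross-talk between the isotopomer
channels (<0.2% at 99% labeling for an 11-carbon nucleoside, and ignored in
the analysis for the same reason), matrix-dependent suppression differences
between nucleosides, or non-hyperbolic saturation. A green test suite
therefore demonstrates that the *mechanics* of the workflow — cancellation,
calibration, propagation — are implemented correctly, not that any real
instrument meets these noise figures.

## Numerical and design choices

* **Linear-window criterion.** The data themselves must say where the curve
  is linear; the package uses back-calculation accuracy on level medians
  (±15% interior, ±20% at the window edges — standard bioanalytical
  acceptance), searching all contiguous runs of at least four levels and
  keeping the longest (ties broken by $R^2$). Raw-signal fits carry an
  intercept (baseline); NIF and UVF fits go through the origin, since a zero
  amount gives a zero ratio/area by construction.
* **Weighting.** $1/x$ across several decades of heteroscedastic data.
* **Blank correction.** The per-session median 12C blank estimates the
  additive baseline and is subtracted from both MS channels; the 13C channel
  of a blank cannot serve as its own baseline because it still carries the
  SIL-IS spike.
* **rRFN uncertainty.** The model-based WLS error is optimistic because NIF
  scatter grows with amount while the top levels carry most of the leverage.
  The reported standard error pools the replicate-level relative scatter
  into one noise CV and propagates it to the slope; it is slightly
  conservative at the bottom of the range, where the baseline inflates
  relative scatter.
* **LOD/LOQ.** $3\sigma$ and $10\sigma$ of blank injections over the raw
  slope. Instrument-specific published limits are configuration, not
  targets.
* **RSD.** Sample (n−1) standard deviation over the mean, in percent.
* **Degenerate inputs.** Zero-variance blanks yield (0, 0) with a warning;
  an all-zero NIF vector yields rRFN 0 with a degeneracy flag; a zero
  denominator in a fold change yields `NA` plus a flag, never infinity;
  nucleosides lacking an rRFN (e.g. dihydrouridine — detectable but not
  weighable) are excluded from absolute results with a warning naming them.
* **Units.** pmol everywhere internally; CSV columns carry unit suffixes.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the default grid (16 levels
× 3 replicates), six-session stability simulations for up to ten
nucleosides, and Monte-Carlo loops of 100–200 repeats for LOD recovery and
spike-in recovery — sizes chosen so the whole suite completes in well under
a minute of simulation time while leaving the stochastic assertions
comfortable margins. Every simulation is seeded; a fixed seed reproduces a
byte-identical measurement table.

```{r example}
model <- instrument_model(nucleosides = c("Am", "C", "U", "G", "A"), seed = 1)
cal <- simulate_calibration(model, nucleosides = "Am", seed = 1)
rf <- build_rf_table(cal)
rf$rf[, c("nucleoside", "rrfn_pmol_inv", "r2", "valid_lo_pmol", "valid_hi_pmol")]
rf$models[, c("channel", "linear_lo", "linear_hi", "decades")]
```

The NIF channel stays linear across the saturation zone that truncates the
raw window — the two-decade extension of the dynamic range that motivates
the whole construction.

## Known limitations

* The hyperbolic suppression model and all noise magnitudes are stipulations
  of the simulator, not fitted to any instrument.
* The UV normalization of relative levels uses the raw canonical sum
  (including SIL-IS material); the SIL-IS fraction is constant across
  samples measured at equal loading and cancels in the fold change, but
  strongly unequal loadings leave a second-order residual.
* Error propagation is first-order on replicate spread; no bootstrap.
* No inferential statistics on fold changes: point estimates with
  replicate-based standard errors only.
* 15N or deuterium labeling is not modeled; the chemistry layer handles
  carbon only.
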