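---
title: "Methods: VLC-PUFA-based phagocytosis quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VLC-PUFA-based phagocytosis quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlcpufa)
```

## The assay model

Retinal pigment epithelium (RPE) cells engulf shed photoreceptor outer
segment fragments (POS) daily. POS membranes are uniquely rich in
very-long-chain polyunsaturated fatty acids (VLC-PUFAs, acyl chains of 28 or
more carbons), while cultured RPE cells carry essentially none of their own.
The assay exploits this asymmetry: after a POS challenge and removal of
surface-bound material, the VLC-PUFA content of hydrolyzed cellular lipid
extracts measures internalized POS. The package implements the computational
half of that assay: from centroided negative-mode full-scan LC-MS runs to
molar amounts and impairment statistics.

Key assumptions, in the order the pipeline relies on them:

1. **Free fatty acids only.** After hydrolysis every analyte is a free fatty
   acid CnH(2n−2d)O2, observed exclusively as its deprotonated ion [M−H]⁻.
   No adducts, no esterified lipids, no isotope pattern beyond the
   monoisotopic peak.
2. **Centroided acquisition.** Spectra are centroided (standard for
   quantification at resolution 70,000); a naive local-maximum centroider is
   available for profile data but is documented as approximate.
3. **Mass accuracy within 5 ppm.** The instrument's calibrated mass error is
   smaller than the extraction window, so a ±5 ppm extracted ion
   chromatogram (EIC) captures the full analyte signal and essentially no
   chemical background.
4. **Retention time identifies the species.** Isomer pairs (22:5, 24:4,
   30:5, 32:4, 32:5) share one m/z and are distinguished only by matching
   detected peaks against a previously established RT library. The omega
   series (n−3 vs n−6) is *not* resolvable by this method and is carried as
   annotation only; gas-chromatographic methods are needed for that
   distinction.
5. **The internal standard cancels run-scale variation.** Fatty acid 21:5 —
   chosen because it does not occur in the samples — is spiked at a known
   amount before extraction; all areas are divided by its area, so any
   global intensity rescaling of a run cancels exactly.
6. **Unit response factors.** Converting a normalized response to moles
   assumes each species ionizes like the internal standard (response factor
   1) unless a per-species factor is configured. No per-species factors have
   been published for this panel, so defaulted molar amounts are relative
   quantities on an absolute scale, not certified absolute amounts. Ratios
   of amounts between conditions — the assay's primary read-out — are
   unaffected by this choice.

## Chemistry conventions

Monoisotopic element masses are stored to eight or more decimals (C 12
exactly, H 1.00782503207, O 15.99491461956 Da). The deprotonated ion is
computed as neutral monoisotopic mass minus the proton mass
(1.007276466879 Da); removing a hydrogen atom and adding back an electron
gives the same value to within the electron binding energy (~1.5e−8 Da),
far below the 1e−4 Th level that matters here. The packaged published m/z
table is a validation *fixture*: the calculator is authoritative and
`check_panel_masses()` diffs the two (all 31 published entries reproduce to
≤ 0.001 at their printed precision, which mixes 3- and 4-decimal entries).

Two conversions use different mass conventions on purpose:

* **m/z axis** — monoisotopic masses, because the mass spectrometer selects
  the monoisotopic peak.
* **grams → moles of spiked standard** — the *average* molar mass from
  standard atomic weights (for 21:5, C21H32O2: 316.485 g/mol), because a
  weighed microgram of material is an isotopic mixture. One microgram of the
  21:5 standard is therefore 3.1597e−9 mol.

Fragment prediction covers the collision-induced dissociation pattern used
for identity confirmation: loss of CO2 (43.9898 Da, printed conventionally
as 44 Da) followed by successive CH2 losses (14.0157 Da steps). Predicted
decarboxylation fragments of the heavy markers agree with measured product
ions to better than 2 ppm (the tests assert 5 ppm, the same tolerance used
for precursor extraction).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tolerance_ppm` | 5 | ppm | The assay's stated extraction tolerance. |
| `rt_tolerance_min` | 0.15 | min | The RT library shows ≤ 0.05 min drift between standards and tissue; ±0.15 gives threefold headroom while staying below the spacing of most isomer pairs. |
| `min_snr` | 3 | — | Conventional detection threshold over baseline, in units of robust noise. |
| `smoothing_window` | 3 | points | Light moving-average smoothing; enough to stop scan noise fragmenting a ~10-point peak, narrow enough not to merge isomers. |
| `is_species` / `is_amount_mol` | 21:5 / 3.1597e−9 mol | — / mol | 1 µg of the spiked standard at its average molar mass. |
| markers | 32:6, 34:4, 34:5, 34:6, 36:6 | — | The VLC-PUFAs absent from cultured RPE but abundant in POS. |

## Peak detection and integration: numerical choices

The published workflow delegated peak picking to vendor software, so the
rules here are the package's own and are chosen for robustness and
testability:

* **Baseline and noise** are the median and scaled median absolute deviation
  of the (smoothed) trace — robust to the peaks themselves, which occupy a
  small fraction of an EIC. A flat trace yields no peaks; traces shorter
  than 5 points are an error.
* **Apexes** are local maxima above `baseline + min_snr × noise`; plateau
  maxima count once.
* **Boundaries** walk outward from the apex until the trace crosses the
  baseline or reaches a *significant* valley — a local minimum below half
  the apex rise. Noise-induced upticks on a flank are walked through, so one
  noisy peak does not fragment; detected intervals that still overlap are
  merged. Partly resolved isomer pairs separated by a deep valley split at
  that valley.
* **Integration** is the trapezoid rule minus a baseline, floored at zero.
  Inside `detect_peaks()` the subtracted baseline is the robust *constant*
  estimate: anchoring a linear baseline at an elevated valley between two
  partly resolved peaks would systematically under-integrate both (the
  perpendicular-drop convention of chromatography software). When the user
  supplies boundaries directly, `integrate_peak()` defaults to the classical
  line between the two boundary points, appropriate for isolated peaks on a
  sloping background; both behaviors are explicit arguments.
* **RT matching** takes the candidate nearest the expected RT within
  tolerance; an exact tie goes to the larger area. Absence of a match is a
  result (`not_detected`), distinct from a detected zero-area peak.

## What the synthetic generator does and does not emulate

`simulate_run()` emulates the acquisition that the pipeline consumes:
centroided negative-mode scans every 0.01 min over 0–8 min (covering the
whole RT library), Gaussian elution profiles (σ = 0.04 min) centered at the
library RTs, centroids at theoretical m/z with a per-species offset drawn
within ±2 ppm (inside the 5 ppm window), multiplicative per-centroid noise,
and flat chemical background placed at least 10 ppm away from every target.
Instrument response is a single sensitivity constant (1e14 counts·min/mol),
and the internal standard is always present. The peak width was chosen so
the closest same-m/z isomer pair in the library remains separable by RT
matching, mirroring the real separation's ability to report those isomers
separately; true peak widths and noise structure of the original instrument
are unpublished, so these are plausible stand-ins.

Scenario arithmetic (`simulate_experiment()`):

* marker amount in challenged cells = dose × n_cells × per-POS amount ×
  `uptake_fraction`;
* knockdown arms scale `uptake_fraction` by (1 − `knockdown_effect`);
* untreated RPE carries LC-PUFAs (20:4…22:6) and *no* species of ≥ 30
  carbons;
* the calibration series converts nmol/L levels to moles via a nominal 1 mL
  sample volume.

Defaults are pinned to the assay's published operating point: per-POS
amounts of 1.20e−15, 2.01e−15 and 9.86e−16 mol for 32:6, 34:6 and 36:6
(34:4 and 34:5, unpublished, are set to the same order of magnitude:
1.5e−15 and 1.8e−15 mol; DHA at 1.5e−14 mol/POS), 20 POS per cell, 1e5
cells (a confluent 48-well), and `uptake_fraction = 0.016` — the value
implied by dividing the published per-cell uptake of 32:6 at 20 POS/cell
(3.80e−16 mol/cell) by the offered per-cell marker load (20 × 1.20e−15
mol); 34:6 and 36:6 give 0.015–0.019 by the same arithmetic.

`noise_cv` is multiplicative per-centroid detector noise. Because such
noise averages out over the ~30 points of a peak, it cannot produce
realistic replicate scatter; the `replicate_cv` scenario therefore *also*
jitters per-replicate amounts by `noise_cv`, emulating biological and
preparation variability, and records the jittered amounts as truth.

Passing tests on this generator demonstrate that the pipeline's arithmetic
and signal processing are correct under the stated model. They do not
demonstrate robustness to what the generator omits: retention-time drift
between runs, peak tailing/fronting, detector saturation, co-eluting
isobaric interference from real matrices, or ionization suppression.

## Problem sizes and determinism

All randomness flows from one seed per run or experiment (an experiment
seeds a single RNG stream that every replicate draws from). The test suite
exercises, among others: end-to-end recovery at zero and 5% scan noise
(asserting ≤ 1% and ≤ 5% relative error), a 0/10/20/40 POS/cell dose series
with three replicates (monotone means, origin-line R² ≥ 0.99), an 82%
knockdown recovered within ±5 points from four replicates per arm, and
100-run sweeps for false-positive VLC-PUFA detection in untreated cells and
for EIC window monotonicity / TIC conservation. These sizes keep the full
suite under a minute on a single CPU while leaving the assertions far from
their tolerances.

## Known limitations

* Molar amounts inherit the unit-response-factor assumption; absolute
  accuracy requires per-species calibration (`fit_calibration()` supports
  this when standards exist).
* The 22:5 isomer pair sits 0.09 min apart — closer than 3σ of the default
  synthetic peak width — and is flagged by the generator as unresolvable by
  design; quantification of such pairs can cross-assign or merge their
  peaks. The marker set avoids all isomer pairs.
* The limit-of-quantification rule (lowest calibration level back-calculated
  within 20% of nominal) is an industry convention, not an
  instrument-specific determination.
* No RT alignment across runs: the pipeline trusts the library within
  ±0.15 min, which is appropriate for a single batch on a stable gradient.
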