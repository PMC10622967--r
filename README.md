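# vlcpufa

Targeted LC-MS quantification of photoreceptor outer segment (POS)
phagocytosis by retinal pigment epithelium (RPE) cells, using
very-long-chain polyunsaturated fatty acids (VLC-PUFAs) as tracers of
internalized cargo.

## The problem and the method

RPE cells in culture carry essentially no endogenous VLC-PUFAs (acyl chains
of 28 or more carbons), whereas POS membranes are rich in them. After an RPE
monolayer is challenged with POS, surface-bound material removed and total
fatty acids extracted and hydrolyzed, the VLC-PUFA content of the cells is
therefore a direct, lipid-based measure of how much POS was engulfed. The
package turns centroided negative-mode full-scan LC-MS runs (m/z 250–800) of
such extracts into assay read-outs. For each free fatty acid denoted C:D
(carbons : double bonds, formula CnH(2n−2d)O2):

- the deprotonated ion is computed from monoisotopic element masses,
  m/z([M−H]⁻) = n·m(C) + (2n−2d)·m(H) + 2·m(O) − m(proton);
- an extracted ion chromatogram (EIC) is built by summing centroid
  intensities within a symmetric ±5 ppm window around that m/z in every
  scan;
- chromatographic peaks are detected against a robust (median/MAD) baseline,
  integrated by the trapezoid rule, and matched to a retention-time library
  (the packaged default covers 20:4 through 36:6, resolving isomer pairs
  that share one m/z purely by RT);
- each peak area A_i is normalized to the co-extracted internal standard
  21:5 (spiked at a known amount, e.g. 1 µg): response_i = A_i / A_IS, and
  converted to moles, n_i = response_i · n_IS / RF_i (response factors
  default to 1);
- assay metrics follow: composition profiles (fractions of the summed
  response), mol per POS particle, mol uptake per cell, percent impairment
  of phagocytosis per marker with an across-marker mean ± SD, and replicate
  coefficients of variation (100·SD/mean).

The marker species for the phagocytosis read-out are 32:6, 34:4, 34:5, 34:6
and 36:6. Identity of targets can be cross-checked via predicted
collision-induced fragments: loss of CO2 (44 Da) followed by a CH2 ladder
(14 Da steps).

A synthetic-data module generates whole experiments (dose series, gene
knockdown, replicate-CV, calibration series) as mzML or TSV runs with known
ground truth, so every stage of the pipeline is testable without instrument
data.

## Worked example

Quantify a simulated MERTK/GAS6/MFG-E8 triple-knockdown experiment
(10 POS/cell, 4 replicates per arm, 5% scan noise):

```r
library(vlcpufa)

mz_deprotonated("32:6")   # 467.3895  — theoretical [M-H]- of the 32:6 marker
fragment_mz("32:6")       # 423.3996  — its decarboxylation fragment

cfg    <- scenario_config("knockdown", pos_per_cell = 10, noise_cv = 0.05)
exp    <- simulate_experiment(cfg, n_replicates = 4, seed = 11)
quant  <- quantify_experiment(exp$runs, exp$design)
report <- assay_report(quant, reference_condition = "control")
report
```

```
Percent change vs reference:
  condition species_label percent_change percent_decrease
1 triple_kd          32:6         -81.39            81.39
2 triple_kd          34:4         -81.92            81.92
3 triple_kd          34:5         -81.74            81.74
4 triple_kd          34:6         -81.93            81.93
5 triple_kd          36:6         -81.76            81.76

triple_kd: mean decrease 81.75% +/- 0.22% (across markers)
```

The generator impaired uptake by 82%; the pipeline recovers 81.75% ± 0.22%
across the five markers. Each marker row reports the drop in the
IS-normalized molar amount of that VLC-PUFA in knockdown versus control
cells; their mean ± SD is the assay's headline impairment figure.

A thin command-line wrapper over the same functions ships in
`inst/cli/vlcpufa` (`masses`, `simulate`, `quantify` subcommands; YAML
config with flag overrides).

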