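---
title: "Methods: multi-omic analytics for enviromimetic organoid screens"
author: "EnviroOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analytics for enviromimetic organoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnviroOmics)
```

## The screen and what the package computes

EnviroOmics implements the analysis chain of an *enviromimetic* screen:
human forebrain organoids derived from a shared panel of iPSC donors are
chronically exposed to chemically defined mimics of environmental risk
factors — a cannabinoid receptor agonist (WIN 55,212-2), the maternal immune
cytokine IL17a, the stress hormone cortisol, nicotine, ethanol and the
opioid endomorphin — alongside a vehicle control, and profiled on three
platforms. The design is paired: every donor contributes one sample to
every treatment arm.

The package covers the post-acquisition computation for all three
platforms:

1. **Targeted metabolomics** — peak heights are extracted from centroided
   MS1 mzML runs against a library of (name, adduct, theoretical m/z,
   polarity, expected retention time) entries; blank runs define per-analyte
   detection thresholds; group-versus-vehicle statistics are computed on the
   threshold-imputed matrix.
2. **Isobaric-label (TMT) proteomics** — a protein x sample intensity
   matrix is filtered to complete cases, log2 transformed, quantile
   normalized, QC'd (CV, correlation), and tested by one-way ANOVA with
   many-to-one post-hoc contrasts plus group-stratified pairwise tests
   versus vehicle.
3. **Flow cytometry** — one-channel DNA-content event sets are deconvolved
   into sub-G1/G1/S/G2M fractions; two-channel cleaved-PARP /
   phospho-H2AX event sets are quadrant gated against unstained-derived
   thresholds, with per-group fold changes and ANOVA + post-hoc tests.

A synthetic-data module generates all three input kinds with known ground
truth, so every stage has a parameter-recovery test surface without any raw
study data.

## Targeted peak extraction

An analyte's m/z window is relative: `[mz(1 − ppm·1e−6), mz(1 + ppm·1e−6))`
with the default `ppm_tol = 5`. The window is **half-open** so that adjacent
windows tile without double counting; retention-time comparisons are
inclusive. Extraction is two-staged:

* **Consensus localization.** In each sample run, the maximum-intensity
  in-window centroid within `search_window = 30` s (0.5 min) of the library
  retention time is located; the study-wide consensus apex is the median of
  these per-run apex times over runs with any signal. Attaching the wide
  window to study-level localization reflects that retention drift is a
  property of the batch, not of one injection.
* **Per-run height.** The reported height is the maximum centroid intensity
  over scans within `apex_tol = 7.5` s of the consensus and inside the m/z
  window. Height (not area) is used: a single maximum is robust to apex
  jitter at these peak widths. Ties at equal intensity resolve to the
  earliest retention time, making extraction deterministic. Blank runs are
  processed identically to samples.

An analyte with no signal in any sample run is reported as absent (height
0 everywhere) rather than an error.

## Detection, imputation and differential statistics

Per analyte, the detection threshold is
`max(sn_multiple x mean(blank heights), floor)` with `sn_multiple = 3` and
`floor = 10,000` (arbitrary intensity units). The blank statistic is the
mean by default (`max` by option). A cell is detected iff its height is at
or **above** the threshold; non-detections are imputed *with* the threshold
value, which keeps fold changes estimable while bounding them: an analyte
undetected in the control arm can never show a finite log2 fold change
above `log2(max observed / threshold)`.

For each treatment group versus vehicle, `log2fc = log2(mean(group) /
mean(control))` on imputed values, with a two-sample pooled-variance t-test
(Welch by option) on the same values. When *every* control sample is
undetected and at least one group sample is detected, the fold change is
reported as `+Inf` with `inf_reason = "control_undetected"` (mirrored for
the reverse); the t-test p-value on imputed values is still reported
alongside, so an "infinite range" analyte carries both a flag and a
significance estimate. Significance is the strict comparison `p < alpha`
(`alpha = 0.05`); no multiple-testing correction is applied in the primary
path, though a Benjamini–Hochberg FDR column is emitted in the volcano
table for users who want it. Degenerate inputs follow fixed conventions:
zero variance in both arms with equal means gives `p = 1`; fewer than two
samples in an arm gives an undefined p-value with a warning, never a call.

Hierarchical clustering of the imputed matrix (Euclidean distance, complete
linkage) provides deterministic row/column leaf orders for heatmap export;
a constant matrix returns the input order with a warning.

## Proteome statistics

Ingest starts at a protein x sample matrix (peptide-to-protein rollup and
search-engine FDR are upstream and out of scope). Proteins with any missing
value are dropped (complete-case rule); intensities are then log2
transformed and quantile normalized, in that order. Quantile normalization
forces all columns to one empirical distribution (each column's sorted
values replaced by row means of the column-sorted matrix, ties receiving
the mean of the tied reference values); it is idempotent and leaves
identical columns unchanged.

QC reports per-sample intensity distributions, per-protein per-group
coefficients of variation computed on **linear** intensities (a CV of log
values is not a CV), group median CVs, and the sample x sample squared
Pearson correlation matrix on log2 values.

Differential testing is two-tiered, mirroring the screen's inclusion rule:
a protein is "differential in group g" iff the one-way fixed-effects ANOVA
omnibus p-value is below alpha **and** the post-hoc contrast of g versus
vehicle is below alpha. The post-hoc is Dunnett's many-to-one single-step
test (via multcomp), the natural choice when every contrast shares the
vehicle control; Holm-corrected pooled t-tests are available by
configuration. Directions are only reported for significant contrasts. The
group-stratified pairwise analysis (two-sample t-test per protein on the
{group, control} columns) is exposed separately, since it answers a
different question and typically calls more proteins.

## Cytometry

**DNA content.** The histogram (256 bins over `[0, 99.5th percentile x
1.1]`) is deconvolved Dean–Jett–Fox style. The dominant mode is taken as
G1; initial estimates come from parabolic interpolation of log counts at
the mode and the left half-maximum width. A Nelder–Mead optimization then
refines (G1 mean, log G1 SD, G2/M-to-G1 ratio mapped into [1.8, 2.2]) with
component amplitudes solved by non-negative least squares at every step
(separable least squares): G1 and G2/M are Gaussians (G2/M width scales
proportionally), S phase is a constant density between the peaks convolved
with the G1 width. The parametrization is scale-free (offsets in units of
the initial G1 width), which makes the fit exactly equivariant under
uniform channel rescaling. The sub-G1 fraction — fragmented DNA, the
screen's proxy of cell death — is the fraction of raw events below
`G1 mean − 3 x G1 SD`; remaining fractions are the NNLS amplitudes
renormalized to the complement. A relative fit residual above 0.1 flags the
result low-confidence. All constants (bins, G2 window, 3-SD gate) are
config-exposed.

**Quadrants.** Events are assigned to exactly one quadrant by strict
exceedance of each channel threshold. Thresholds come from the configured
upper quantile (default 0.999) of an unstained sample — the "no
background" gating idea made explicit. Percentages are computed per sample,
averaged within group, and fold changes are group mean over control mean; a
zero control mean yields a flagged, undefined fold change. ANOVA plus the
same Dunnett-style post-hoc machinery runs on the per-sample percentages.

## The synthetic generators: what they emulate, and what they do not

**Metabolome runs.** Each sample run carries one Gaussian chromatographic
peak per analyte present in its group: fixed FWHM 12 s (the field gives no
peak shape; a Gaussian is the minimal standard), apex height
`base_height x 2^effect` times log-normal noise (`noise_cv = 0.05`), apex
RT jittered (`rt_jitter_sd = 1` s), and a per-run centroid m/z jittered at
1 ppm SD — the mass accuracy of a well-calibrated high-resolution
instrument, which keeps essentially every centroid inside the ±5 ppm
extraction window. Scan grid spacing is 1 s with both polarity streams
sharing the grid (stored as co-timed scan pairs; retention times are
strictly increasing within each polarity). Blanks carry only uniform
background centroids below `floor/3`, so blanks can never trigger
blank-based detection — this isolates the threshold logic in tests. Each
run owns an RNG stream keyed by `(seed, sample_id)`, so adding samples
never perturbs existing ones. The default effect matrix encodes the
screen's published per-group log2 changes for the 18-analyte panel, with
guanosine triphosphate absent in the vehicle (and in the WIN arm) to
exercise the Inf convention; default design: 7 groups x 5 donors + 3
blanks. Not emulated: profile-mode spectra, isotope patterns, co-eluting
interferences, MS2.

**Proteome matrix.** Log2 intensities are per-protein base levels
(N(20, 2)) plus per-donor offsets (SD 0.1, shared across arms — the paired
design) plus group effects on a randomly affected subset (default 400 of
4857 proteins, effect SD 0.5 log2 units) plus multiplicative noise
(CV 5 %); cells go missing completely at random (rate 0.01, which leaves
roughly three quarters of proteins complete in a 28-sample design). Not
emulated: intensity-dependent missingness, batch structure, shared-peptide
effects.

**Cytometry events.** DNA content draws multinomially across compartments:
Gaussian G1 (CV 5 %), Gaussian G2/M at exactly twice G1, S uniform between
the peaks convolved with the G1 noise, sub-G1 uniform on `(0.2, 1 − 3 cv) x
G1`. The control preset is (0.05, 0.60, 0.20, 0.15); the WIN preset
multiplies sub-G1 by 2.29. Two-channel events are four log-normal clusters
(log10 centers 1.5 / 2.9, SD 0.12) with design gates at 100 channel units,
placed ≥ 3 cluster SDs from every center so gating ground truth is
unambiguous; control quadrant probabilities put the PARP-positive rate at
1.58 % of cells with 0.4 % double-positive, and per-group fold presets span
1.71–14.56 (PARP+) and 1.80–11.13 (double-positive) with the WIN arm at the
maxima. Not emulated: spillover/compensation, doublets (the generator emits
singlets only), acquisition drift.

Because the generators draw from exactly the model families the analytics
assume (Gaussian peaks, log-normal noise, Gaussian/uniform DNA components),
passing recovery tests demonstrates correctness of the implementation under
its stated model — not robustness to the asymmetric peaks, drifting
baselines or skewed populations of real instruments.

## Numerical and design choices

* Half-open m/z windows, inclusive RT comparisons, inclusive detection at
  the threshold, strict `p < alpha`, strict `>` quadrant positivity: every
  boundary has one documented convention, and the boundary cases are
  tested.
* Ties in extraction resolve to the earliest RT; clustering and NNLS are
  deterministic; the Dunnett p-values use multivariate-t integration whose
  Monte Carlo error (~1e-4) is made reproducible by per-stage seeding in
  the pipeline.
* Infinite fold changes take precedence over the imputed finite estimate
  when the control arm is entirely undetected, and are placed at a sentinel
  abscissa (largest finite |log2fc| + 1) in volcano exports.
* Fold-change direction is defined group-over-control everywhere and
  stated in the output schema, avoiding sign ambiguity between tables.
* The pipeline writes every stage artifact before the next stage reads it,
  and the run report's counts are recomputable from those artifacts; two
  runs with the same config and seed are byte-identical (verified by
  checksums in the test suite).

## Problem sizes used in the tests and acceptance script

Matrix-level statistical checks use 2,000 null analyte tests (n = 5 per
arm), 1,000 null proteins (7 groups x 4 donors) for ANOVA calibration and
gated-Dunnett family-wise error, and 200 spiked analytes at the screen's
effect scale (−0.30 log2, CV 5 %). Cell-cycle recovery uses 20 seeds at
20,000 events; quadrant preset rates use 100,000 events. Oracle-equivalence
checks run 100 random runs/event tables against brute-force
implementations. The end-to-end determinism check runs the full default
configuration (38 mzML runs, 4,857 proteins, 70 cytometry samples) twice.
These sizes give stable Monte Carlo estimates (binomial SE ≤ 0.007 on the
calibration rates) at desk scale.

## Known limitations

* The consensus-apex scheme handles global retention drift, not per-run
  drift beyond ±7.5 s of the consensus; no RT alignment is attempted.
* Peak height (max centroid) slightly underestimates the true apex when
  the apex falls between scans — under 0.5 % at the default 1 s grid and
  12 s FWHM.
* The DNA-content model assumes a resolvable dominant G1 mode and a G2/M
  peak within [1.8, 2.2] x G1; aneuploid or heavily apoptotic samples
  violating this are rejected or flagged rather than silently fit.
* The unstained-quantile gate mislabels the configured complement (0.1 %)
  of negative events by construction; preset-rate checks therefore use the
  generator's design gates.
* Covariate-adjusted re-testing of metabolites (count-model based) and
  pathway/enrichment analysis are out of scope.
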