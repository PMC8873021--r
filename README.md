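# EnviroOmics

Multi-omic analytics for *enviromimetic* organoid screens: studies in which
human forebrain organoids from a shared donor panel are chronically exposed
to chemically defined mimics of environmental risk factors (a cannabinoid
agonist, IL17a, cortisol, nicotine, ethanol, an opioid agonist) alongside a
vehicle control, and profiled by targeted LC/MS metabolomics, isobaric-label
(TMT) proteomics and flow cytometry. The package is for analysts who need
the post-acquisition computation of such a screen as tested, reusable
functions rather than one-off scripts — and for method developers who need
fully synthetic inputs with known ground truth.

## What it computes

**Targeted metabolomics.** Peak heights are extracted from centroided MS1
mzML runs against a metabolite library: for analyte *i* with theoretical
m/z *mᵢ*, centroids inside the half-open window
*[mᵢ(1 − ppm·10⁻⁶), mᵢ(1 + ppm·10⁻⁶))* (default ±5 ppm) are considered; a
study-wide consensus apex is the median per-run apex RT within ±0.5 min of
the library RT, and the reported height is the maximum in-window centroid
within ±7.5 s of that consensus. Blank runs define per-analyte detection
thresholds

&nbsp;&nbsp;&nbsp;&nbsp;*Tᵢ = max(3 × mean(blankᵢ), 10 000)*,

cells below *Tᵢ* are flagged not-detected and imputed with *Tᵢ*, and each
treatment group is tested against vehicle: *log2FC = log₂(mean꜀ᵣₒᵤₚ /
mean꜀ₒₙₜᵣₒₗ)* with a pooled-variance t-test, strict *p < 0.05*, and a ±Inf
fold-change convention when one arm is entirely undetected.

**Proteomics.** Complete-case filtering, log2 + quantile normalization,
CV/correlation QC, one-way ANOVA with Dunnett many-to-one post-hoc versus
vehicle (a protein is differential in group *g* iff omnibus *p < α* and
post-hoc *p(g) < α*), plus group-stratified pairwise t-tests.

**Flow cytometry.** Dean–Jett–Fox-style DNA-content deconvolution
(Gaussian G1 and G2/M, broadened-rectangle S, NNLS amplitudes inside a
Nelder–Mead fit; sub-G1 = events below G1 − 3 SD) and two-channel cleaved
PARP / phospho-H2AX quadrant gating (strict thresholds from an unstained
sample's 99.9th percentile) with fold changes and ANOVA + post-hoc versus
control.

**Synthetic data.** Generators for mzML run sets, protein matrices and
cytometry event tables with known ground truth; defaults reproduce the
screen's study conditions (7 arms, paired donors, an 18-analyte panel with
published effect sizes, control PARP⁺ rate 1.58 %, a 2.29-fold sub-G1
increase in the cannabinoid arm).

## Worked example

```r
library(EnviroOmics)

design <- StudyDesign(c("vehicle", "WIN", "IL17a"), donors = 3, blanks = 2,
                      seed = 1)
sim  <- simulateMetabolomeRuns(design, defaultMetaboliteTruth())
sim$runs[["WIN_D1"]]
#> MsRun 'WIN_D1' (sample): 886 centroids, 526 scans

mset <- buildIntensityMatrix(sim$runs, defaultMetaboliteLibrary())
mset <- applyDetection(mset, computeThresholds(mset))
res  <- differentialAll(mset)
subset(res, analyte %in% c("L-Phenylalanine", "Guanosine Triphosphate"))
#>                   analyte group     log2fc      p_value significant         inf_reason
#> 7  Guanosine Triphosphate   WIN  0.0000000 1.000000e+00       FALSE               none
#> 11        L-Phenylalanine   WIN -0.2149073 2.997303e-02        TRUE               none
#> 25 Guanosine Triphosphate IL17a        Inf 2.570116e-06        TRUE control_undetected
#> 29        L-Phenylalanine IL17a -0.2701504 1.844349e-02        TRUE               none
```

L-phenylalanine comes back significantly decreased in both arms (its
configured effects are −0.30 and −0.32 log2 units; at n = 3 donors the
estimates carry visible noise). Guanosine triphosphate is undetected in
every vehicle run, so the IL17a arm reports the infinite fold-change flag
rather than a finite estimate, while the WIN arm — where the analyte is
absent too — correctly reports nothing.

```r
set.seed(1)
fit <- fitDnaContent(simulateDnaContent(cytometryPreset("WIN"), g1_mean = 100))
fit
#> CellCycleFit: sub-G1 0.118 | G1 0.557 | S 0.188 | G2/M 0.137
#>   G1 99.9 +/- 4.9, G2 200.5 +/- 9.9, residual 0.041
```

The WIN preset's true fractions are (0.1145, 0.559, 0.186, 0.140); each is
recovered within ~0.004 at 20,000 events.

The whole chain — generation, mzML writing/reading, quantification, all
three statistics stages, JSON report — runs from one config:

```r
report <- runPipeline(defaultPipelineConfig(seed = 1), "pipeline_out")
```

or from a shell via `inst/scripts/run_pipeline.R`. Identical config + seed
gives byte-identical outputs.

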