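# ftirms

Dual-modality discrimination of fracture-related infection (FRI) from
matched control plasma: mid-infrared (FTIR) spectroscopy of dried plasma
films on one branch, TMT LC-MS/MS protein abundance ratios on the other,
with a shared sparse-classification and bootstrap-evaluation core.

Diagnosing FRI early is hard: the established blood markers (CRP, ESR,
WBC) are weak predictors, and confirmatory tests are invasive. Two
minimally invasive candidates are the plasma mid-infrared "fingerprint" —
the summed absorbance of all MIR-active bonds in 400–4,000 cm⁻¹ — and the
plasma proteome. This package implements a complete, reproducible analysis
pipeline for a matched case-control design (13 FRI / 13 control pairs,
three replicate wells per sample), together with a synthetic paired-cohort
generator so that every stage is testable end to end without patient data.

## What the pipeline computes

**FTIR branch.** Per replicate spectrum: normalization to unit area under
the curve; additive log-ratio (ALR) against the potassium-thiocyanate
(KSCN) internal-standard band (plasma is spiked 2:1 with KSCN, giving a
reference peak near 2,060 cm⁻¹); Savitzky–Golay filtering; removal of the
KSCN band. Replicates are averaged to sample level and compressed with the
orthonormal DCT-II

&nbsp;&nbsp;X_k = √(2/N)·C_k·Σₙ xₙ·cos(π/N·(n+½)k),  C₀ = 1/√2, C_k = 1 (k>0),

followed by low-frequency/near-zero-variance filtering and univariate
screening (pooled t-test and Cohen's d, retaining |d| > 0.5).

**Classifier.** Elastic-net logistic regression minimizing

&nbsp;&nbsp;L(β) = (1/N)·Σ −log p(yᵢ|xᵢ) + λ(α·‖β‖₁ + (1−α)/2·‖β‖₂²),

fit by cyclic proximal-Newton coordinate descent (compiled) along a
decreasing λ path with a hard cap of 50 nonzero coefficients.

**Evaluation.** Pair-level bootstrap: each draw resamples the matched
pairs, trains on the in-bag samples and scores the out-of-bag samples
(AUROC, sensitivity, specificity at p > 0.5). A session is B = 100 draws;
S = 100 sessions under independent seeds are pooled by inverse-variance
fixed-effect meta-analysis with CI95 = mean ± 1.96/√Σ(1/vᵢ). Features are
ranked by selection frequency (top-40 reported).

**MS branch.** The identical screening/classification/pooling core applied
to natural-log protein abundance ratios (no Savitzky–Golay, no DCT — MS
features form no continuous spectrum).

**Cross-modal association.** Canonical correlation analysis
(ρ from the SVD of Σ_XX^(−½)Σ_XYΣ_YY^(−½)) with permutation p-values, and
a cross-modal autoencoder (three dense layers into a 2-node bottleneck,
mirrored decoder reconstructing the *opposite* modality).

**Cohort statistics.** Exact two-sided Fisher tests on 2×2 demographic
tables and two-sided matched t-tests on paired continuous variables.

## Worked example

```r
library(ftirms)

cfg <- runConfig(bootstrap = list(sessions = 10L, resamples = 50L))
ds  <- generateDataset(syntheticConfig(seed = 8, effect_size = 1.0))
out <- ftirPipeline(ds$spectra, cfg)
out$pooled
#> PooledMetrics (ivw pooling, 10 sessions):
#>   auroc        0.843  CI95 (0.834, 0.852)
#>   sensitivity  0.878  CI95 (0.864, 0.893)
#>   specificity  0.631  CI95 (0.610, 0.652)
head(attr(out$ranking, "top"))
#> [1] "dct_101" "dct_584" "dct_365" "dct_490" "dct_62"  "dct_718"
```

The generator planted a class effect of Cohen's d = 1.0 on the amplitudes
of three plasma bands; the pooled out-of-bag AUROC of 0.843 shows the
pipeline recovers it. The CI95 quantifies bootstrap-resampling noise
around this one cohort's estimate — not cohort-to-cohort sampling
uncertainty, which at 13 pairs is an order of magnitude larger (the
methods vignette quantifies this distinction).

The cohort table statistics:

```r
counts <- read.csv(system.file("extdata", "table2_counts.csv",
                               package = "ftirms"))
cohortReport(counts = counts)[2:3, ]
#>        variable          p                   method
#> 2       implant 0.04717997 Fisher exact (two-sided)
#> 3 fracture_type 0.09565217 Fisher exact (two-sided)
```

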