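---
title: "Dual-modality FRI discrimination: models, choices, and what the synthetic benchmarks show"
author: "ftirms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality FRI discrimination: models, choices, and what the synthetic benchmarks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirms)
```

## The problem and the design

Fracture-related infection (FRI) is diagnosed late because the routine
blood markers are weak. Two plasma-based alternatives are compared here:
the mid-infrared absorbance fingerprint of dried plasma films (FTIR,
400–4,000 cm⁻¹, three replicate wells per sample) and TMT LC-MS/MS
protein abundance ratios. The design is a matched case-control cohort:
13 FRI patients each paired with an infection-free control on age, time
after surgery and fracture region. The package implements the full
analysis for both modalities plus their cross-modal association, and a
synthetic generator that emulates the design so every claim below is
backed by a test this package actually runs.

## Spectral preprocessing

Each replicate spectrum passes through, in order:

1. **Area normalization** — division by the trapezoidal integral over the
   wavenumber grid, removing film-thickness/optical-path scale.
2. **Additive log-ratio (ALR) to the internal standard** — plasma is
   spiked 2:1 with potassium thiocyanate, whose C≡N stretch gives an
   isolated peak near 2,060 cm⁻¹ in an otherwise quiet window. Each
   channel becomes `log(x_i / r)` with `r` the mean absorbance in the
   KSCN band (default 2,000–2,150 cm⁻¹). The band *mean* is used rather
   than peak height or area because it is robust to the exported channel
   spacing; any global rescaling of a spectrum cancels exactly. Values
   are clipped at `1e-8 × max(row)` before the log: dried-film baselines
   can dip to or below zero, and the clip floor is recorded in the
   configuration.
3. **Savitzky–Golay filtering** (window 11 channels, order 3, derivative
   0 by default) for baseline drift and noise. The filter's window,
   order, and whether it is run as a smoother or a derivative filter are
   exposed because common FTIR practice varies; the defaults are the
   plain smoother. Edges are handled by polynomial fits of the terminal
   windows (`signal::sgolayfilt`).
4. **KSCN band removal** — the internal-standard channels are deleted so
   the classifier cannot use the spiked peak.

Replicates are then **averaged to sample level**. Averaging happens
before classification so that bootstrap resampling operates on samples,
never on replicates of the same sample split across training and test
sets. All downstream stages are deterministic, so the pipeline output
depends on the replicates only through their mean, and permuting
replicate rows changes nothing (both are tested).

## DCT compression and screening

Sample spectra are compressed with the orthonormal DCT-II,

$$X_k = \sqrt{2/N}\, C_k \sum_{n=0}^{N-1} x_n
  \cos\!\left(\tfrac{\pi}{N}(n+\tfrac12)k\right),\qquad
  C_0 = 1/\sqrt2,\; C_k = 1\ (k>0).$$

This convention is self-inverse-transpose and energy-preserving
(Parseval holds to 1e−10 in the tests, and the transform matches a direct
O(N²) evaluation to 1e−12). Frequency k = 0 (the spectrum mean, which the
ALR step has already pinned) is dropped, as is any coefficient whose
across-sample variance falls below 1e−8 of the largest across-sample
variance. Features are then screened one by one with a pooled-variance
two-sample t-test and Cohen's d
(`d = (mean_FRI − mean_control)/s_pooled`), retaining |d| > 0.5. The
retention rule is two-sided: a feature separating in the "protective"
direction is as informative as one elevated in FRI. Pooled (Student)
rather than Welch t is used so the test and the effect size share one
variance estimate; both are configurable. No multiplicity correction is
applied at this stage — screening feeds a classifier, it does not assert
discoveries.

## The capped elastic net

The classifier is logistic regression with the elastic-net penalty,
minimizing

$$L(\beta) = \frac1N \sum_i \big[-y_i \log p_i - (1-y_i)\log(1-p_i)\big]
 + \lambda\big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big),$$

with α = 1 the lasso and α = 0 ridge. α is not dictated by the method
itself; the default is 0.5 and it is recorded in every results file.
Features are standardized to zero mean and unit variance inside the fit
(a shared λ across heterogeneous features is meaningless otherwise);
coefficients are reported on the standardized scale and prediction
applies the stored standardization.

The optimizer is cyclic coordinate descent with exact per-coordinate
curvature and a backtracking acceptance test, so the objective is
non-increasing by construction — asserted after every sweep — and the
solution matches an independent proximal-gradient minimizer of the same
objective to 1e−4 on random instances (tested), as well as the reference
implementations of the lasso and ridge limits. The λ grid descends
log-uniformly from the data-derived λ_max (the smallest all-zero-solution
penalty) over 20 points to λ_max·10⁻³. The grid is explored at a loose
tolerance (1e−4 on the largest coefficient update) and the selected point
is refit to 1e−7 from a warm start; the loose exploration only has to
rank path points by in-sample deviance and count nonzeros.

The **cap of 50 used coefficients** is enforced by walking the path from
heavy to light regularization and stopping before the nonzero count would
exceed 50; among admissible path points the one with the best in-sample
deviance is kept. With many screened features this selects the
least-regularized admissible point — i.e. the cap itself, not λ tuning,
is what limits model complexity, which is exactly the role the cap plays
in this design.

## Bootstrap sessions and fixed-effect pooling

The resampling unit is the **matched pair**, preserving the design: a
bootstrap draw samples 13 pairs with replacement, trains on the in-bag
samples, and evaluates on the out-of-bag pairs (which always contain both
classes — each pair contributes one FRI and one control). Empty
out-of-bag draws are redrawn and counted. A session is B = 100 draws
under one seed; S = 100 sessions run under seeds `config$seed + 1:S`
(both scaled to B = 50, S = 10 in the packaged benchmarks, which keeps
the full 40-cohort benchmark suite within minutes while leaving every
qualitative conclusion unchanged). Per metric, a session contributes its
mean m and the squared standard error of that mean, v = var/B; sessions
are pooled as a fixed-effect meta-analysis: mean = Σ(m/v)/Σ(1/v), CI95 =
mean ± 1.96/√Σ(1/v), clipped to [0, 1]. Unweighted pooling
(`pooling = "mean"`) is available since the exact weighting behind such
session meta-analyses is often unstated. Sensitivity and specificity are
taken at predicted probability 0.5. Features are ranked by selection
frequency over all resamples of all sessions, ties broken by feature id
for determinism.

## Where the screening sits, and what the CI means — two caveats the package quantifies

**Screening scope.** The printed analysis order screens features once,
on the full cohort, before the bootstrap ("global" scope, the default
here). Because the out-of-bag samples participated in that screen, the
out-of-bag estimates are optimistic: on *label-exchangeable null* cohorts
(no planted effect) the default pipeline still reaches pooled AUROC near
0.9. Screening inside each bootstrap draw ("resample" scope, one config
switch) removes the leakage — across null cohorts the session AUROC then
averages 0.50 (tested) — but at 13 + 13 samples against ~860 candidate
coefficients it also removes essentially all power: scanning the entire
λ path under honest in-resample screening, for α from 0 to 1, the
out-of-bag AUROC of a planted d = 1.0 band effect never exceeded ~0.54.
Both scopes are first-class; the default follows the printed order and
this paragraph is the package's warning label for it.

**Fixed-effect CIs on one cohort.** All sessions resample the *same*
realized cohort, so Σ(1/v) grows with S·B and the CI width shrinks to
±0.01–0.02 — it measures bootstrap-resampling noise only. Any AUROC
estimated from 26 samples carries irreducible sampling error of roughly
0.1 (Hanley–McNeil), so the pooled value of a single null cohort
scatters between ~0.3 and ~0.7 across generator draws while its CI stays
narrow. A narrow fixed-effect CI from repeated resampling of one small
cohort must therefore not be read as cohort-to-cohort generalization
uncertainty. The packaged benchmarks state this quantitatively: the
"CI95 covers 0.5 on 90% of null cohorts" calibration check *fails* for
this estimator family at this sample size — under either screening scope
— and the package reports the measured coverage rather than widening the
interval to hide it.

## The synthetic paired-cohort generator

`generateDataset()` draws, per cohort: 13 matched pairs; nine Gaussian
plasma bands (amide I ≈ 1,650, amide II ≈ 1,545, amide III ≈ 1,240,
CH-stretch 2,850–2,960, carbohydrate ≈ 1,080, COO⁻ ≈ 1,400, broad
amide A/OH ≈ 3,300 cm⁻¹) with log-normal between-sample amplitudes
(CV 0.15, 30% of log-variance shared within a pair to reflect the
matching); a KSCN internal-standard peak at 2,060 cm⁻¹ whose amplitude
is independent of class (tested); per-replicate pipetting jitter
(CV 0.02), a random quadratic baseline, and i.i.d. channel noise; grid
400–4,000 cm⁻¹ at 4 cm⁻¹ (the nominal spectral resolution). The class
effect shifts the log-amplitudes of three bands by `effect_size`
between-sample log-SDs; a Monte-Carlo test confirms the realized
amplitude Cohen's d averages the nominal value within ±0.15. Proteins
are log-normal ratios (CV 0.25), with the first 32 of 1,000 accessions
shifted by Δ = 0.8 log-SDs in FRI — matching the scale at which plasma
proteomics of this contrast reports differential abundance. Band
positions and all rates are configurable; the defaults above were fixed
once as a plausible plasma film and are not calibrated to any measured
spectrum.

What the generator does **not** emulate: water-vapor and CO₂ artifacts,
scattering baselines beyond a low-order polynomial, peak-position shifts,
correlated (non-spherical) channel noise, TMT channel effects or missing
proteins. Passing tests therefore demonstrate the *statistical* pipeline
under its own assumptions, not instrument robustness.

## Discriminant visualization

The selected features are compressed by column-centered SVD (15
components by default), and a Fisher discriminant is trained in the
component space. A two-class problem has one discriminant; the plotted
second axis is the leading principal direction of the within-class
residuals made within-class-uncorrelated with the first. An "orthogonal
residual PC in the whitened space" sounds more principled but is
degenerate — sphering makes the within-class residuals exactly isotropic,
so that construction has no preferred direction; the package's axis-2 is
the well-posed alternative. Axis 1 is scaled to unit within-class SD,
making it exactly invariant to invertible feature rescaling (tested).
Class clouds get 95-percentile confidence ellipses: sample mean and
covariance scaled by a bivariate-t radial quantile, `2·qF(level; 2, n−1)`,
which approaches the χ² ellipse as n grows and widens for the n = 13
class clouds of this design.

## Cross-modal association

CCA is run on the most discriminatory raw wavenumber channels and
proteins (top 8 per modality by |d|; 8 ≲ n/3 keeps the within-set
covariances invertible at n = 26), standardized, with canonical
correlations from the SVD of Σ_XX^(−½)Σ_XYΣ_YY^(−½); near-singular
covariances receive a recorded ridge. Significance is by permutation of
the rows of Y: p = (1 + #{ρ_perm ≥ ρ_obs})/(1 + n_perm), valid and never
below 1/(1+n_perm). Note that pre-selecting features on the class labels
makes the *embedding vs class* question optimistic in-sample — the
association test between modalities (the permutation test) is unaffected,
since permutation breaks exactly the X–Y pairing being tested.

The cross-modal autoencoder sends each modality through three tanh dense
layers (64, 16, 4) into a 2-node bottleneck; the mirrored decoder
reconstructs the *opposite* modality, so the bottleneck can only succeed
by carrying shared structure. Training is full-batch Adam (step 0.01,
2,000 epochs, seed-deterministic initialization) on the summed MSE of
both paths, with the step size backed off whenever the loss rises, so
the smoothed trajectory is non-increasing. When the two modalities truly
share a 2-D latent, joint reconstruction error approaches zero (tested);
class separation of the bottleneck is judged by the AUROC of a Fisher
discriminant on the 2-D embedding, compared against label permutations
rather than against 0.5 (an in-sample 2-D discriminant on 26 points is
optimistic even for pure noise).

## Cohort statistics

2×2 categorical tables use the exact two-sided Fisher rule that sums the
hypergeometric probabilities of all tables (same margins) no more likely
than the observed one, with a 1e−7 relative slack for floating-point
ties; this is verified against complete table enumeration for every 2×2
table with total ≤ 40, and reproduces all printed cohort p-values at
their printed precision from the packaged count table. Paired continuous
variables use the two-sided matched t-test (one-sample t on within-pair
differences, df = n−1). Continuous variables published only as
means (SD) cannot be re-tested without pair-level data and are not
fabricated.

## Numerical choices and degenerate inputs

* Coordinate descent: tolerance 1e−7 on the largest coefficient update
  (path exploration at 1e−4), at most 1,000 sweeps per λ, objective
  monotonicity asserted every sweep.
* Degenerate (zero-pooled-variance) features are errors in the scalar
  effect-size functions but are dropped with a warning by the matrix
  screen, and in-bag-constant columns are removed before each bootstrap
  fit.
* A bootstrap draw in which no feature passes the screen falls back to a
  constant-prevalence model (AUROC 0.5 by the tie rule) and is counted.
* Fisher tests reject zero margins; pooling rejects zero-variance
  sessions; ellipses reject degenerate covariances; all-removed
  frequency filters are errors carrying the largest observed variance.
* Every stochastic step (generator, bootstrap, permutations, autoencoder
  initialization) flows from seeds recorded in the configuration, and a
  rerun from a results record's config and seeds reproduces every
  per-session metric bit for bit (tested).

## Known limitations

* At 13 + 13 samples, out-of-bag discrimination of realistic band
  effects is weak without the (optimistic) global screen; the package
  exposes both screening scopes rather than pretending one setting gives
  both calibration and power.
* The fixed-effect CI quantifies resampling noise of one cohort only.
* The autoencoder is a fixed small architecture without hyperparameter
  search or a validation split; it answers "is there easily learnable
  shared structure", not "what is the best cross-modal map".
* The DCT feature space is not interpretable in terms of individual
  wavenumbers; selected coefficients mix all channels by construction.
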