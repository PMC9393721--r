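---
title: "Methods: multimodal hippocampal radiomics with slow-5 ALFF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal hippocampal radiomics with slow-5 ALFF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the conventions the package
fixes where the field admits several, and the design decisions behind the
synthetic-cohort generator. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## 1. The problem and the model

Hippocampal texture in structural MRI is an established radiomic marker of
Alzheimer's disease, but it is weak for the prodromal stage (amnestic mild
cognitive impairment), where functional change precedes structural change.
The package therefore treats the amplitude of low-frequency fluctuation
(ALFF) of resting-state fMRI — restricted to the slow-5 band, 0.01–0.027 Hz —
as a second *image* from which the same radiomic features are extracted, and
builds diagnostic signatures from structural features, ALFF features, and
their union ("combined").

A signature is an L1-penalized logistic regression on a filtered feature
subset; its linear predictor is the **radscore**:

$$\text{radscore}(x) = \beta_0 + \sum_{f \in S} \beta_f \, z_f(x),$$

where $z_f$ is the z-normalized feature value (normalization parameters
estimated on training rows only) and $S$ is the set of features surviving
mRMR filtering and LASSO shrinkage. Discrimination is summarized by the AUC
of the radscore, averaged over 10 random stratified 70/30 splits.

Assumptions worth making explicit:

* the diagnosis is binary per contrast (case vs control); a three-class
  model is deliberately out of scope;
* features are comparable across subjects once z-normalized — hence
  fixed-bin-number discretization (scale-free) rather than fixed bin width;
* motion artifacts are handled by exclusion (QC) and by regression of the
  Friston-24 expansion, not by scrubbing or interpolation;
* the supplied masks are trusted; segmentation itself is out of scope
  (`dice()` is provided to validate externally produced masks, and
  `resample_mask()` to carry a structural-space mask into functional space
  with a precomputed affine; in the synthetic space the two grids coincide).

## 2. Functional preprocessing and ALFF

The order of operations in `subject_alff()` is: discard the first
`n_discard` volumes (default 10), build the Friston-24 matrix
$[R(t),\,R(t{-}1),\,R(t)^2,\,R(t{-}1)^2]$ from the trimmed motion trace,
regress each within-mask voxel on an intercept, a centered linear trend, the
confounds and optional tissue mean series, and Fourier-transform the
residuals.

**Amplitude convention.** ALFF is the mean over in-band frequency bins of the
single-sided amplitude $2\lvert X(f)\rvert/N$. The literature divides over
amplitude vs $\sqrt{\text{power}}$ and sum vs mean; any fixed choice is
equivalent downstream because z-normalization absorbs scale. The convention
is fixed so that a unit-amplitude bin-aligned sinusoid with 7 in-band bins
yields ALFF $= 1/7$ exactly, which the tests assert to $10^{-10}$.

**Band edges.** A discrete bin at frequency $f = k/(N\,T_R)$ is in-band iff
$0.01 \le f \le 0.027$ (closed interval, no interpolation); the DC bin is
always excluded. With the default TR = 2 s and 200 retained volumes the band
contains the 7 bins at 0.010–0.025 Hz.

**Motion QC.** Framewise displacement follows the Power convention:
$FD_t = \sum\lvert\Delta d_t\rvert + 50\,\text{mm}\sum\lvert\Delta
\theta_t\rvert$ with rotations in radians, $FD_1 = 0$. Exclusion applies any
of: max $\lvert$translation$\rvert$ > 3 mm, max rotation > 3°, or **mean** FD
> 0.5 mm. Mean (not maximum) FD is the default because that is the common
toolchain behaviour; it is configurable (`qc_thresholds(fd_summary =
"max")`).

**No ALFF standardization** (division by the global mean) is applied by
default; it is available via `compute_alff(standardize = TRUE)` but changes
nothing after z-normalization.

## 3. The 101-feature roster

The roster is fixed and documented rather than inferred: 13 intensity
features and 88 textural features per modality and ROI.

* **Intensity (13):** mean, median, min, max, range, variance, SD (population
  $1/n$ convention), skewness, excess kurtosis (both 0 for a constant ROI),
  energy, histogram entropy (on the discretized levels), 10th and 90th
  percentiles (type-7 quantiles).
* **GLCM (26 × 2 distances = 52):** joint maximum/average/variance/entropy,
  energy, contrast, dissimilarity, four inverse-difference variants, inverse
  variance, correlation, autocorrelation, cluster tendency/shade/prominence,
  sum and difference average/variance/entropy, the two information measures
  of correlation, and the maximal correlation coefficient. Matrices are
  summed over the 13 unique directions of the 26-neighbourhood with pairs
  counted in both orders, then features are computed once from the aggregated
  symmetric matrix (not averaged per direction). The same roster is computed
  at offset distances 1 and 2 (`_d2` suffix): multi-distance co-occurrence
  statistics are standard radiomic practice and capture texture at two
  spatial scales; the distance-1 block is the primary one and carries the
  canonical feature names.
* **GLRLM (18):** the sixteen standard run-length statistics plus the mean
  gray level (GLA) and mean run length (RLA) — the first moments that the
  GLV/RLV variances are taken around. Runs are counted per direction over
  the same 13 directions and the matrices summed; run percentage is
  normalized by `13 × n_voxels`.
* **GLSZM (18):** the size-zone analogues (zones are 26-connected components
  of equal level; a single matrix, as connectivity has no direction).

Degenerate conventions: GLCM correlation is 1 when the gray-level variance is
0 (single occupied level); the information measures are 0 in that case; the
maximal correlation coefficient is 1 with fewer than two occupied levels;
skewness/kurtosis are 0 at zero variance; inverse variance sums over
off-diagonal cells only.

**Discretization.** Fixed bin number, default $N_g = 32$, applied within-ROI:
level $= 1 + \lfloor N_g (x - \min)/(\max - \min)\rfloor$ with the maximum
mapped to $N_g$. This makes all texture features invariant to monotone affine
intensity transforms — necessary because structural and ALFF intensities have
incomparable units. The brute-force oracle tests run at $N_g \le 4$ on
4×4×4 ROIs, where exhaustive enumeration is feasible.

## 4. Signature construction

The training chain (`fit_signature()`) estimates everything on training rows
only; a leakage-sentinel test perturbs test rows and asserts the fitted model
is bit-identical.

* **z-normalization** with sample ($n-1$) standard deviations; zero-variance
  features are zeroed with a warning (kept for index stability).
* **SMOTE** after normalization (so Euclidean neighbourhoods are not
  dominated by large-scale features) and before feature selection: synthetic
  minority rows interpolate between a minority row and one of its $k = 5$
  nearest minority neighbours, with $k$ reduced when the minority class is
  smaller than $k+1$.
* **mRMR** with the MID (difference) criterion: features are discretized into
  3 states at mean ± SD; the first pick maximizes mutual information with the
  label, each next pick maximizes relevance minus mean redundancy with the
  already-selected set; exactly 20 features are returned, with ties broken by
  column name for determinism. The quotient criterion (MIQ) and a
  pure-relevance ranking are available by flag, since the textual description
  of the published procedure is ambiguous between greedy mRMR and
  relevance-only top-20.
* **LASSO** logistic regression (the outcome is a binary diagnosis, so the
  binomial family is the natural reading) via `glmnet::cv.glmnet`, 10-fold
  CV with stratified fold assignment drawn from the seed, $\lambda$ at the
  minimum mean CV deviance. The minimum-deviance rule (not 1-SE) is chosen
  because it keeps more features and makes the selected set more stable
  across repetitions in the simulation studies; it is configurable in
  principle by refitting at any $\lambda$.

## 5. Evaluation

* **Splits:** per class, `round(0.7 * n)` subjects to training; splits are
  shared across ROIs and modalities within a contrast and repetition so that
  DeLong comparisons are paired on identical subjects.
* **AUC** by midrank Mann–Whitney (ties weighted 1/2), with a 95% normal
  interval from the DeLong variance, truncated to [0, 1].
* **Accuracy** is reported at the Youden-optimal threshold of the training
  ROC, frozen and applied to the test set — the published tables report
  accuracy without defining a threshold, so a deterministic, training-only
  rule is used.
* **DeLong comparisons** are computed per repetition on training scores by
  default (the published z-values accompany training AUCs); `delong_on =
  "test"` switches to test scores.
* **Wilcoxon**: rank-sum for two independent groups; exact null distribution
  when both groups have ≤ 10 observations and no ties, otherwise the
  tie-corrected normal approximation without continuity correction; all-tied
  input yields p = 1.
* **Spearman**: Pearson correlation of midranks (the printed rank-formula),
  p from the t approximation with $n-2$ degrees of freedom.
* No multiple-testing correction is applied anywhere ($\alpha = 0.05$
  throughout), matching the source analysis.
* The "12 signatures" layout is 2 contrasts (AD vs NC, aMCI vs NC) × 2 ROIs
  (left, right hippocampus) × 3 modalities (structural, ALFF, combined).
  Bilateral analysis is supported either as the union mask
  (`combine_bilateral()`, pooled extraction) or by concatenating left and
  right feature vectors — the union is the default because it keeps the
  feature count at 101/202.

## 6. The synthetic-cohort generator

`generate_subject()` emulates, per subject:

* a structural volume: baseline 100 + white noise (SD `noise_sd`, default 1);
  inside each ROI a Gaussian random field smoothed with kernel width
  $0.6 + \texttt{texture\_effect}$ voxels for patient groups (0.6 otherwise),
  re-standardized within the ROI and scaled to SD 10, is added on top of the
  noise. Standardizing the field keeps the first-order statistics free of
  group information, so the texture dial moves GLCM correlation/entropy-type
  features without moving the mean — the two dials are orthogonal by
  construction. The observation noise is retained inside the ROI so that no
  feature is exactly constant across subjects.
* a functional series: baseline 100 + linear drift (`drift_slope` per
  volume) everywhere + white noise; ROI voxels additionally carry the sum of
  three sinusoids at 0.0125, 0.02 and 0.025 Hz with subject-random phases —
  frequencies chosen to be bin-aligned at the default TR = 2 s and 200
  retained volumes, so spectral assertions are exact — whose amplitude is
  spatially modulated by a smooth log-normal field (giving the ALFF map
  realistic within-ROI texture) and scaled by $1 + \texttt{alff\_effect}$ in
  patient groups;
* a 6-column motion trace: a small random walk (steps 0.02 mm / 2·10⁻⁴ rad),
  optionally with planted step or square-wave displacements to trigger each
  QC rule deliberately;
* an MMSE-like clinical score: group means 17.512 (AD), 26.200 (aMCI),
  29.023 (NC) with SDs 5.084 / 0.881 / 0.902, i.e. a monotone function of
  group severity plus Gaussian noise, so feature–score correlations are
  recoverable by construction.

The default cohort is 84 AD / 50 aMCI / 44 NC, TR = 2 s, 210 volumes. The
default grid (20×16×12 voxels, two ellipsoidal ROIs of ≈ 110 voxels) emulates
the *functional* resolution, at which a human hippocampus spans roughly 100
voxels; structural images are generated on the same grid for simplicity.

What the generator does **not** emulate: brain anatomy and tissue contrast,
scanner artifacts, slice-timing effects, spatially correlated noise,
physiological confounds, registration error between modalities (the grids
coincide), and realistic feature covariance structure. Passing the recovery
tests therefore shows that the pipeline is correct and well calibrated — not
that the published clinical effect sizes are reproduced; the published AUCs
come from private clinical data and are out of reach by construction.

**Seed protocol.** One master seed per cohort; subject $i$ uses
`derive_seed(master, i)`, a Lehmer-style integer hash computed in exact
double arithmetic, so any subject is reproducible in isolation and results
are bit-identical across platforms. Library code never perturbs the caller's
RNG (`with_seed` saves and restores `.Random.seed`).

## 7. Numerical and testing choices

* Simulation sizes: the null-calibration and effect-recovery studies use 20
  subjects per group and 20 (null) / 10 (per grid point) cohorts with 2
  repeated splits per cohort; the effect grid is `alff_effect` ∈ {0, 0.5, 1}
  and the dual-effect study uses 0.5/0.5. These sizes give Monte-Carlo
  standard errors of a few hundredths of an AUC, small enough to separate
  chance (0.5) from planted effects.
* Null calibration is asserted against the 95% Monte-Carlo interval of the
  pooled mean test AUC; monotonicity in the planted effect is asserted up to
  one Monte-Carlo SE (the response saturates near AUC 1 at the top of the
  grid).
* The per-feature null-uniformity check compares Wilcoxon rejection rates
  against the **exact discrete** null CDF (at 4 vs 4 subjects the exact
  rank-sum p-value takes nine values; comparing against a continuous uniform
  would be a category error).
* Type-I error of the DeLong and Wilcoxon implementations is checked at
  2,000 null replicates each; the DeLong variance is additionally
  cross-checked against a paired bootstrap and against `pROC`.
* GLCM/GLRLM/GLSZM implementations are vectorized (array shifting, ordered
  run-length encoding, `igraph` connected components); the test oracles are
  independent naive triple loops and an explicit flood fill.

## 8. Known limitations

* The exact composition of the 88 textural features in the motivating study
  is not public; the roster here is a documented, IBSI-consistent stand-in
  that contains all features the study names explicitly. Absolute feature
  values are therefore not comparable to other toolkits feature-for-feature,
  though the named formulas follow the standard definitions.
* `resample_mask()` implements nearest-neighbour resampling with a supplied
  affine; registration estimation is out of scope.
* The Wilcoxon normal approximation is used whenever either group exceeds 10
  observations; for borderline sizes with heavy ties the exact-mid-p
  refinement is not implemented.
* SMOTE assumes a Euclidean feature space; it is applied to z-normalized
  features, which is the standard mitigation, but no categorical handling
  exists (all radiomic features are continuous).
* The pipeline holds an entire cohort's 4D images in memory when driven via
  `generate_cohort()`; for large real cohorts, per-subject streaming via
  `subject_alff()`/`extract_feature_vector()` is the intended route.
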