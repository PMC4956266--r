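---
title: "Methods: latent-variable classification of serum metabolomics profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-variable classification of serum metabolomics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboclass)
```

This vignette documents the statistical machinery in `metaboclass`: the
models, their assumptions, the tunable parameters and their defaults, the
numerical conventions, and the known limits of what the test suite
demonstrates. It is written for an analyst who wants to understand *why*
the package computes what it computes, not just how to call it.

## The data model

The unit of analysis is a samples × metabolites table of GC-MS peak areas
(relative intensities, arbitrary units). The package assumes intensities
are **positive and multiplicative**: a sample's overall level is the
product of an injection/ion-suppression factor, a per-metabolite baseline,
a group effect, and measurement noise, all acting multiplicatively. On the
log scale this is an additive Gaussian model, which is why univariate
screening and effect directions are computed on log intensities. Missing
values are rejected rather than imputed: the pipeline targets a processed,
complete peak table, and silent imputation would blur the distinction
between measurement and model.

Seven cohort labels are recognized (`SLE_G1/G2/G3`, `pSS`, `SSc_lc/dc`,
`HV`); `pool_sle_subgroups()` collapses the lupus phenotype subgroups into
one SLE group and the two cutaneous sclerosis subtypes into one SSc group,
mirroring the analytic decision to pool phenotypes whose profiles overlap.

## Internal-standard normalization

Between-sample intensity differences in GC-MS arise mainly from inlet
efficiency and ion suppression, which scale every compound of a sample by
a common factor. The isotopically labeled internal standards (IS) are
spiked at constant amount, so their observed variation *is* that factor.
`fit_is_normalizer()` estimates it as follows:

1. divide each IS column by its mean (unit-mean scaling), so no single
   high-abundance standard dominates — the data supply no reason to weight
   standards unequally;
2. fit a one-component **non-centered** principal component model to the
   scaled IS matrix; for a purely multiplicative structure this matrix is
   rank-1 and the magnitude of the t₁ score is exactly the per-sample
   factor;
3. rescale the factors to median 1, keeping normalized data on the
   original intensity scale. Dividing by the rescaled |t₁| is the package's
   documented reading of "t₁ magnitude as a general intensity measure";
   the absolute scale of the factor is arbitrary.

On simulated cohorts the estimated factors correlate with the true
injection factors at r > 0.95 and normalization strictly reduces every
feature's within-group coefficient of variation (tested over 20 seeds).

## NIPALS PCA, Q², DModX and DCrit

`fit_pca()` extracts components one at a time by the NIPALS power
iteration with deflation. Conventions:

- **Scaling.** Stored means/SDs always come from the training rows only.
  Default is centering + unit variance (the convention of the major
  commercial chemometrics package); Pareto and no scaling are available,
  and every model records its scaling.
- **Sign.** Each loading's largest-magnitude element is positive, making
  scores reproducible across runs.
- **Convergence.** Relative score change < 1e-12, up to 5000 iterations.
  The loose-looking cap is deliberate: on near-degenerate residual
  matrices (e.g. white-noise folds inside cross-validation) the two
  leading eigenvalues can be nearly tied and the power iteration's
  direction drifts within their span long after the explained variance has
  converged. If the cap is reached in that state the current direction is
  accepted — any direction in a degenerate eigenspace reconstructs the
  data equally well — otherwise fitting fails loudly.

**Cross-validated Q²** (`q2_pca()`) uses deterministic round-robin folds in
row order (default 7; `folds = N` gives leave-one-out), refits scaling and
model per fold, and projects held-out rows onto the training loadings.
Because that projection fits `a` free score parameters per held-out row of
`K` values, the raw reconstruction error is optimistic by a factor
`(K−a)/K`; PRESS therefore carries the correction `K/(K−a)`. Without it,
pure-noise data yield a spurious Q² ≈ A/K; with it, structureless data
give Q² ≤ 0 and planted low-rank structure still gives Q² near 1.

**Distance to model.** An observation's absolute DModX is the standard
deviation of its residual off the model plane, `√(SS(e)/(K−A))`; the
normalized DModX divides by the pooled training residual
`s₀ = √(SS(E)/((N−A−1)(K−A)))` (centered models; `N−A` otherwise). Three
finite-sample corrections restore a common scale between training and new
observations:

- training rows (residuals shrunk by the fit): multiply by `√(N/(N−A−1))`;
- new rows (residuals inflated by the estimated subspace and center):
  divide by `√(1 + (A+1)/N)` — the usual prediction-variance leverage,
  which matched the empirically measured inflation (≈1.019 at N = 200,
  K = 30, A = 3) to three decimals;
- under unit-variance scaling, new rows are additionally divided by
  `√((N−1)/(N−3))`, the expected inflation `E[s²/ŝ²]` from estimating the
  column SDs on `N` training rows.

The membership threshold `DCrit = √F₁₋α(K−A, (N−A−1)(K−A))` comes from an
F test at significance level α (default 0.05). The exact small-sample
correction used by the commercial implementation is unpublished, so these
conventions are validated by calibration simulation: on a 3-latent-dimension
Gaussian factor model (200 training rows, 30 variables, mean-centered,
A = 3), the fraction of 2000 fresh in-class rows beyond DCrit is within
±0.015 of α for α ∈ {0.01, 0.05, 0.10}.

Two regimes are known to push the empirical rejection above the nominal
level, and are deliberately *not* hidden by further tuning: (i)
unit-variance scaling with small classes (~50 rows) overdisperses the
scaled residual through the sampling noise of the per-column SDs (observed
rejection 0.08–0.10 at α = 0.05); (ii) fitting components to structureless
pure noise lets the model chase the largest noise directions, so `s₀`
underestimates the prediction error. Both reflect the approximate nature
of F-based critical distances in SIMCA practice.

## SIMCA soft classification

`fit_simca()` fits one PCA model per class on that class's rows only. A
sample belongs to a class iff its normalized DModX is within the class's
DCrit — membership in zero, one, or both classes is possible, which is the
point of *soft* classification and what a Coomans' plot displays (the two
per-class distances as coordinates, the two critical distances as lines).

Per-class component counts default to the count (1–5) maximizing
leave-one-out Q²; the cohorts this targets are small (18–30 samples per
class), where one or two components are typically supportable.

`loo_validate_simca()` computes cross-validated performance: each class
member is held out, the class model refit without it, and its membership
re-assessed — the retained fraction is the class's sensitivity. Samples of
the other class are evaluated against the full class model (leave-one-out
removal is only defined for a model's own training members); the rejected
fraction is the specificity. External groups (e.g. pSS/SSc screened
against SLE and HV models) are classified with `classify_simca()`, and the
mean of the per-model rejection fractions is reported as the aggregate
external specificity.

## OPLS-DA

`fit_oplsda()` implements single-response orthogonal projections to latent
structures discriminant analysis. The response is coded +1 (disease) / −1
(control), so the natural class-belonging threshold on the predicted
response is zero; a predicted value of exactly zero (e.g. the training
mean row) is assigned the positive class by a documented tie rule. With
`w ∝ X'y`, the predictive score automatically satisfies `t'y ≥ 0`, so
positive p(corr) always means "higher in the disease class" — this keeps
multi-contrast profile comparisons sign-consistent without post-hoc flips.

Each of the `n_orth` orthogonal components (default 1, a common choice for
two-class metabolomics contrasts) removes the part of the X-loading
orthogonal to `w`; its scores are uncorrelated with both the response and
the predictive score (asserted to 1e-8 in the tests). The discriminatory
profile is `p(corr)ⱼ = cor(t_pred, xⱼ)` on the original scaled columns,
bounded in [−1, 1]. Note a subtlety: a feature *identical* to the response
coding has p(corr) equal to `cor(t_pred, y)`, which is below 1 on noisy
data — p(corr) measures alignment with the predictive score, not with the
class labels.

**Cross-validation** uses class-stratified round-robin folds (default 7)
and refits everything, including the column scaling, inside each training
fold — slightly stricter than common practice, but it removes a leakage
channel at negligible cost. Q² = 1 − PRESS/SS(y−ȳ).

**CV-ANOVA** compares PRESS against the total response variance:
`F = ((SS−PRESS)/df_m)/(PRESS/df_e)` with `df_m = 1 + n_orth` and
`df_e = N − 1 − df_m`, p from the upper F tail. When cross-validation does
no better than the mean (PRESS ≥ SS), F truncates at zero and p = 1.
Calibration simulation shows the consequence: under the null the test is
*conservative* (measured type-I error ≈ 0 at nominal 0.05 over 200 null
datasets), because null cross-validated predictions are almost always
worse than the mean. A significant CV-ANOVA is therefore trustworthy; a
non-significant one is weak evidence of absence.

**ROC curves** for OPLS-DA models use the cross-validated predicted
response as the score. The AUC is the trapezoidal area of the threshold
sweep, which equals the Mann–Whitney concordance probability with half
credit for ties (verified against a brute-force pair count). For PCA
overview models, per-score ROC panels orient each score so AUC ≥ 0.5 and
report the chosen sign.

## Univariate screening

`significance_table()` runs a Welch two-sample unequal-variance t-test per
feature on log intensities, flagging p < α (default 0.05) with the
direction from the mean log difference. No multiple-testing adjustment is
applied by default — the screening mirrors raw p < 0.05 usage in this
literature and is meant to annotate the multivariate profile, not to make
marginal discovery claims; Benjamini–Hochberg adjustment is available
behind a flag. On a null cohort of 243 features, ~12 false positives are
expected and observed.

## GC-MS identification

`match_value()` scores two stick spectra on the 0–999 scale: peaks are
aligned on a nominal-mass grid (m/z rounded to integers, the GC-EI
convention), weighted as `mzᵐ·Iᵖ` with the Stein–Scott exponents
m = 3, p = 0.6 as defaults (the field convention for "higher m/z peaks
weigh more"; both configurable), and compared by squared cosine scaled to
999 and rounded half-up. The squared-cosine form makes the score symmetric,
invariant to intensity scaling, and exactly 999 for self-matches.
`retention_index()` is the van den Dool/Kratz piecewise-linear
interpolation over a C10–C40 alkane ladder, with no extrapolation.
`identify_spectrum()` accepts the best-matching library entry within the
±10 index-unit retention window (ties broken by smaller RI deviation, then
name) if its match value reaches the configured minimum (default 700, a
conventional "good match" floor).

## The synthetic cohort generator

`generate_cohort()` draws
`xᵢⱼ = fᵢ · bⱼ · exp(δ_g(i),j) · exp(εᵢⱼ)` with:

| parameter | default | meaning |
|---|---|---|
| `group_sizes` | 10/10/10 SLE, 20 pSS, 9+10 SSc, 18 HV | the study design |
| `n_features` / `n_identified` | 243 / 73 | putative vs identified analytes |
| `n_internal_standards` | 11 | IS columns, no group effect |
| `injection_sigma` | 0.25 | SD of log fᵢ ~ lognormal |
| `noise_sigma` | 0.15 | SD of log-scale measurement noise |
| `baseline_log_mean_range` | [8, 13] | per-feature log baselines (natural log of peak area) |
| `block_correlation` | 0 | optional equicorrelation of noise within a chemical class |

A log-normal multiplicative model was chosen because GC-MS peak areas are
positive and scale with injected amount; the source describes the
variation mechanism but no distribution, so the distributional form and
the two SDs are the package's own realistic-by-construction choices, fixed
once. Effect magnitudes |δ| ∈ [0.4, 1.0] make planted effects detectable
at these group sizes without being trivial.

`default_effect_spec()` plants the qualitative disease biology the
analysis should recover: versus healthy volunteers, SLE has exactly 5
up-shifted analytes (urea, uric acid, cystine and two fatty acids) and 15
down-shifted (tryptophan at δ = −1.0, the top discriminator by
construction; arginine, ornithine, hypoxanthine, cysteine, tyrosine,
fumaric acid and a broad amino-acid panel) — the urea-cycle, xanthine
oxidase and redox patterns. SSc down-shifts fewer amino acids and turns
arginine up; pSS raises several organic acids including fumaric acid, so
its p(corr) sign flips between the SLE and pSS contrasts. Per-metabolite
fold-changes and variances are not reported in the source literature;
these values are documented stand-ins, returned as ground truth alongside
every generated cohort.

What the generator does **not** emulate: chromatographic co-elution and
peak-shape artifacts, drug metabolites (naproxen/paracetamol confounding),
age/sex structure in the intensities, batch drift beyond the single global
factor, and heavier-than-log-normal tails. Passing tests therefore show
the machinery is correct and well-calibrated under the stated model, not
that real cohorts will reach the same Q² or specificity.

## Pipeline and determinism

`run_pipeline()` executes: normalization → restriction to identified
features (the IS columns are consumed by normalization first — they must
be present when the normalizer is fit, and are dropped in its output) →
subgroup pooling → phenotype overview PCA → four-group overview PCA with
per-score ROC → SIMCA SLE/HV with LOO plus soft prediction of pSS/SSc →
OPLS-DA contrasts (default SLE/SSc/pSS vs HV, SLE vs pSS, SLE vs SSc) →
significance tables → joint cross-contrast p(corr) table. Steps whose
groups are absent are skipped with a logged notice. All fold assignments
are deterministic functions of row order, so identical input and
configuration give byte-identical numeric artifacts; the provenance block
records seed, scaling, feature set and package version.

Cross-validation honesty is tested on null cohorts (planted effects
removed): the median cross-validated Q² over 20 seeds is ≤ 0.05 even
though the training R²Y is substantial — the signature of per-fold
refitting without leakage.

## Problem sizes in the tests

The test suite and acceptance checks run at the scale of the study design
they emulate: cohorts of 87 samples × 254 columns, 20-seed medians for
stochastic properties, 2000 held-out rows per calibration replicate. These
sizes were chosen as the smallest at which the binomial/sampling error of
each property is well below its decision band.

## Known limitations

- The F-based DCrit is approximate; its calibration is demonstrated for
  mean-centered models with genuine latent structure and degrades with
  unit-variance scaling at small N (documented above).
- CV-ANOVA is conservative under the null by construction.
- p(corr) is a correlation, not an effect size; strongly correlated
  features share rank.
- The identification module assumes nominal-mass electron-impact spectra;
  no isotope-pattern or accurate-mass logic.
- No batch/drift correction beyond the global injection factor; no
  missing-data support by design.
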