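---
title: "Modelling cognitive reserve as moderation of pathology effects on cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive reserve as moderation of pathology effects on cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogreserve)
```

## The scientific problem

Some older adults maintain good cognitive performance despite substantial
Alzheimer's-disease (AD) pathology. The cognitive-reserve (CR) framework
formalizes this as *moderation*: a candidate reserve measure should change the
slope of the relationship between brain pathology and cognition, not merely
correlate with cognition. `cogreserve` implements a multivariate version of
this moderation analysis for task-fMRI data: it searches for a voxel-level
activity pattern, expressed during successful memory encoding, whose
expression attenuates the effect of AD pathological load on a cognitive
composite. The package also provides everything around that core: a
one-dimensional pathological-load score from fluid and imaging biomarkers,
behavioural/motion quality control, bootstrap voxelwise inference, individual
CR scores, and cross-sectional plus longitudinal validation models.

Because the clinical cohorts this methodology targets are access-restricted,
the package ships a seeded synthetic-cohort generator with known ground truth.
Every stage of the pipeline is tested against planted truth, end to end.

## Pathological load (PL)

Three continuous ATN measures — CSF A$\beta_{42:40}$ ratio (A), CSF p-tau181
(T) and TIV-corrected bilateral hippocampal volume (N) — are z-scored and
reduced to a single coordinate per subject. The default reduction is exact
t-SNE to one dimension (`Rtsne`, perplexity 30, at least 1000 iterations); a
first-principal-component alternative is provided and the two agree closely
(|r| > 0.8 under the generator's moderate-noise conditions, typically ≈ 0.99).

Two conventions that the underlying idea leaves open are fixed here:

* **Initialisation.** The 1-D t-SNE embedding is initialised from the first
  principal component (scaled to SD $10^{-4}$). A random start frequently
  leaves "straggler" points on the wrong side of a cluster gap; a PC1 start is
  deterministic, globally ordered, and removes that artefact. With this
  initialisation the embedding's ranks are also stable under affine rescaling
  of an input biomarker (the z-scoring absorbs the rescaling; the remaining
  floating-point perturbations no longer flip the layout).
* **Orientation and scale.** A 1-D embedding's sign is arbitrary. The score is
  oriented to increase with the p-tau z-score (p-tau rises with pathology; the
  A$\beta$ ratio serves as a fall-back anchor with reversed sign) and min-max
  rescaled to $[0,1]$: 0 is the least, 1 the most affected subject in the
  fitting sample.

t-SNE has no out-of-sample map; new subjects are scored by their nearest
neighbour in biomarker z-space (documented limitation — use `method = "pca"`
when exact out-of-sample scoring matters). A companion *atrophy score*
rescales $-\mathrm{HV}/\mathrm{TIV}$ to $[0,1]$ for subjects without CSF data.

## The multivariate reserve model

Let $\beta_i$ be a subject's subsequent-memory contrast value at voxel $i$
(inside a task-active mask), $PL$ their pathological load, and $y'$ their
(Box-Cox-transformed) cognitive composite. The fitted model is a
principal-component moderation regression

$$ y' = b_0 + \sum_{p=1}^{P} b_{1,p}\,PC_p +
   \Big(b_2 + \sum_{p=1}^{P} b_{3,p}\,PC_p\Big)\,PL^2 + c\,COV + \varepsilon $$

where $PC_p$ are scores on the leading $P$ eigen-images of the mean-centred
contrast matrix, and $COV$ contains age (centred), sex, TIV (centred) and site
dummies. Education is deliberately **not** a covariate: it is a reserve proxy
reserved for validation. Pathology enters only through its square — the
quadratic form predicts the composite better than the linear form and a single
pathology predictor keeps the interaction model interpretable.

The moderation coefficients are mapped back to voxel space,
$w_i = \sum_p b_{3,p} V_{p,i}$ (and analogously $a_i$ from $b_{1,p}$), giving
the group-level reserve pattern. Per-subject scores are inner products with
the raw contrast map: $CR = \sum_i w_i \beta_i$ and $BAE = \sum_i a_i \beta_i$
(the additive "brain-activity effect"). Correlation-based downstream analyses
are unaffected by the raw-versus-centred choice, which shifts scores by a
constant.

Numerical conventions: the PCA is a singular-value decomposition of the
column-centred matrix; each component's sign is fixed by making its
largest-magnitude loading positive, so $w$ is reproducible across platforms;
rotating the retained components by any orthonormal matrix leaves fitted
values and $w$ unchanged (tested).

### Choosing the number of components

$P$ is selected by 10-fold cross-validation. The PCA basis is refit inside
every training fold — projecting held-out subjects onto a basis estimated from
all subjects would make held-out $R^2$ optimistic. Held-out performance is
$R^2 = 1 - SS_{res}/SS_{tot}$ about the held-out mean. The curve of mean
held-out $R^2$ against $P$ typically rises steeply while informative
components enter and then plateaus with small noisy fluctuations; a strict
argmax therefore wanders far up the plateau and inflates the variance of $w$.
The default selection is the **one-standard-error rule**: the smallest $P$
whose mean $R^2$ is within one standard error of the maximum
(`rule = "max"` restores the literal argmax, ties to the smallest $P$).
The default candidate grid is $1..\min(20, \lfloor N/10\rfloor)$.

### Outcome transformation

The PACC5 composite is the mean of five subtest scores, each z-scored against
the cognitively unimpaired subsample. Before model fitting it may be Box-Cox
transformed, $y' = ((y + s)^\lambda - 1)/\lambda$, with $\lambda = 2.8$ by
default. The composite is negative for impaired subjects, so a shift is
required; the default policy is $s = 1 - \min(y)$, making the smallest shifted
value exactly 1. $\lambda$ and $s$ are recorded in the fit.

## Voxelwise inference

Uncertainty in $w$ is assessed by bootstrap: subjects are resampled with
replacement, the regression coefficients are re-estimated on the **fixed**
full-sample PCA basis, and $\hat w$ is re-projected. Per voxel, the $B$
replicates are sorted and the 95% interval is read off order statistics
$\lfloor 0.025B\rfloor + 1$ and $\lceil 0.975B \rceil$ (126 and 4875 at
$B = 5000$); a voxel is significant when its interval excludes zero.

Two properties of this procedure matter for interpretation:

* **The basis is held fixed.** Re-estimating coefficients only mirrors the
  intended procedure, and $w$ itself is invariant to sign flips and reordering
  within the retained span. The cost is that PCA-estimation error — a dense,
  systematic tilt of the retained subspace that grows with voxel noise and
  with $V/N$ — is invisible to the resampling. `refit_basis = TRUE` propagates
  it as a sensitivity analysis (back-projected maps are span-invariant, so
  component order/sign need no alignment across iterations).
* **Voxel errors are correlated.** Significance at all voxels is driven by the
  same $P$ coefficients, so false positives arrive in dense batches: in a
  given dataset the null-voxel significance rate is close to 0 or jumps to
  tens of percent, while its average across datasets sits at the nominal 5%.
  Calibration must therefore be assessed as an average over independent
  cohorts (the test suite uses 80), never from a single dataset.

Significant voxels are grouped into sign-homogeneous connected components
(26-connectivity by default, configurable to 6 or 18), components smaller than
50 voxels are dropped, and each cluster is summarized by size, mean $w$, peak
voxel (largest $|w|$, reported in grid and mm coordinates) and *percent
concordant* — the share of voxels whose $w$ sign matches the sign of the
group-mean contrast there (zero group-means count as discordant by
convention).

## Quality control

Subjects are excluded when any statistic strictly exceeds its threshold:
(1) more than 8 indoor/outdoor classification errors; (2) absolute response
bias above 1.5, with bias defined here as mean confidence rating minus the
scale midpoint 3 (the symmetric choice on a 1–5 scale); (3) framewise
displacement above 0.5 mm in any single EPI or above 0.2 mm in more than 2% of
EPIs, with FD the mean absolute between-volume difference of the six rigid-body
parameters and rotations converted to arc length on a 50 mm sphere
(configurable); (4) extreme outliers (beyond $Q_1 - 3\,IQR$ or $Q_3 + 3\,IQR$
across subjects, per voxel) in more than 10% of masked voxels, zero-IQR voxels
never flagging. Quartiles use the linear-interpolation convention
(`quantile` type 7) throughout. Subjects with missing inputs are flagged
unevaluable rather than silently kept. The arcsine parametric modulator
$\arcsin((x-3)/2)\cdot 2/\pi$ is provided as a utility for building
subsequent-memory regressors from confidence ratings.

## Validation of the CR score

* **Cross-sectional.** A separate moderation model,
  $y' = b_0 + b_1 BAE + b_2 PL^2 + b_3\,CR\cdot PL^2 + c\,COV + \varepsilon$,
  with the CR score entering only through the interaction (no CR main effect;
  a flag adds one for sensitivity analysis). A variant replaces $PL^2$ by the
  squared atrophy score. An education model adds education and
  education$\times PL^2$ to the quadratic pathology model.
* **Association with a proxy.** Pearson correlation between CR score and years
  of education, with Fisher-z interval (`cor.test`).
* **Longitudinal.** A linear mixed model of repeated PACC5 on
  atrophy$^2$ × time × CR (with all nested two-way terms), BAE and BAE × time,
  plus covariates, with per-subject random intercept and slope (unstructured
  covariance, REML; `lme4`). Fixed-effect t-tests use Satterthwaite degrees of
  freedom (`lmerTest`). A likelihood-ratio comparison against a
  random-intercept-only model (both refit by ML) justifies the random slope;
  its 5% critical value is boundary-corrected (mixture of $\chi^2_1$ and
  $\chi^2_2$, ≈ 5.14). If the full random structure fails, the model falls
  back to a diagonal random-effect covariance and, in the degenerate
  zero-variance case, to OLS for the fixed effects, recording which path was
  taken. Time is years since baseline, continuous and uncentred.
* **Outlier policy.** CR scores above $Q_3 + 3\,IQR$ are excluded before all
  CR-score analyses.

## The synthetic-data generator

`simulate_cohort()` draws a cohort with the statistical structure the analysis
assumes, with every planted quantity recorded in `$truth`:

* a latent severity per subject, uniform on $[0,1]$; ATN biomarkers that are
  strictly monotone in severity before noise, with population means and
  spreads chosen to resemble an AD-continuum memory-clinic cohort (age
  69.7 ± 5.6 y, education 14.6 ± 2.9 y, ≈ 54% female);
* a planted reserve pattern $w^\star$ of truncated-Gaussian signed blobs
  (two positive "inferior-temporal-like", one negative "precuneus-like";
  $\sigma = 2.5$ voxels, support ≈ 69% of the mask, unit norm; exact zeros
  outside the truncation radius so the support is well defined);
* contrast maps = group mean map + expression $\cdot\, w^\star$ + nuisance
  latent components orthogonal to $w^\star$ + i.i.d. voxel noise. Expression
  is sample-centred, so it equals $\langle w^\star, \beta -
  \bar\beta\rangle$ exactly when voxel noise is off;
* baseline cognition
  $y = b_0 + b_2\,\mathrm{sev}^2 + m\cdot \mathrm{expr}\cdot\mathrm{sev}^2 +
  \text{covariate effects} + \varepsilon$ — the moderation structure the model
  is built to find, with severity in the role of PL;
* education as a noisy linear function of expression hitting a target
  correlation (default 0.3);
* longitudinal decline whose atrophy dependence is attenuated by expression
  ($g_0 + g_a\,\mathrm{atr}^2 + g_{3}\,\mathrm{expr}\cdot\mathrm{atr}^2$ per
  year, plus random intercept/slope and visit noise);
* behavioural/motion records with planted exclusion-rule failures that exceed
  each threshold by construction, while all other subjects are safe on every
  rule by construction, so the exclusion round trip is exact.

Every stage draws from a sub-seed derived from the master seed by a fixed
offset, so any stage is reproducible in isolation and the whole bundle is
bit-identical across runs.

**Default calibration.** Defaults were chosen so that the stated statistical
properties of the method hold by design under the default conditions, and are
not revisited: moderation strength 1.5, cognition noise SD 0.8, contrast voxel
noise SD 0.02 (small relative to the structured per-voxel signal but an order
of magnitude below the component scale — low per-voxel SNR with a resolvable
component structure), nuisance loading SDs (3, 2.2, 1.6, 1.25). Two of these
choices are load-bearing and worth spelling out. First, the nuisance loading
SDs are kept away from the expression SD (1): a near-tie in component
variances splits the planted pattern across two eigen-images, and a truncated
basis then leaves a dense residual that degrades both recovery and inference.
Second, the fixed-basis bootstrap is blind to basis-estimation error, which
scales with voxel noise; contrast noise must be small enough that this
invisible error stays below the bootstrap's own coefficient uncertainty, or
voxelwise false positives concentrate outside the planted support.

**What the generator does not emulate.** No EPI time series, hemodynamics,
spatial autocorrelation of voxel noise, scanner/site effects on images (site
enters cognition only, as an additive offset), non-Gaussian biomarker tails,
practice effects on repeat testing, or dropout. Passing tests therefore show
that the estimators recover the structure they assume, at realistic sizes and
noise — not that real acquisitions satisfy those assumptions.

## Problem sizes used by the test suite

The tests and the acceptance script run the pipeline at sizes chosen to make
the Monte-Carlo assertions stable: pattern recovery on 10 cohorts of
$N = 300$ subjects and ≈ 3000 mask voxels with cross-validated $P$; bootstrap
false-positive calibration over 80 null cohorts at $B = 1000$ and
planted-support precision over 10 cohorts at $B = 500$; CI-coverage
calibration of the cross-sectional and mixed-model interaction terms over 200
null simulations each; zero-noise exactness at $N = 120$. The oracle
equivalence check uses a $V = 6$, $N = 60$ problem where the component model
with $P = V$ must reproduce brute-force voxelwise-interaction OLS to
$10^{-8}$.

## Known limitations

* The CR pattern is multivariate: single-voxel significance and cluster
  descriptives are transparency aids, not independent localized tests.
* Fixed-basis bootstrap intervals understate uncertainty when per-voxel noise
  is large relative to the component structure (see above); use
  `refit_basis = TRUE` to gauge the difference.
* The PL score is cross-sectional and collapses the ATN system onto one axis;
  it indexes overall severity, not event order.
* t-SNE scores are only nearest-neighbour extensible to new subjects.
* The moderation model is symmetric in its interaction: identical fits are
  consistent with other causal orderings of pathology, activity and cognition.
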