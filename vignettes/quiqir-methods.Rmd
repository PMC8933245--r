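---
title: "Quality-index weighted analysis of quantitative MRI maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-index weighted analysis of quantitative MRI maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quiqir)
```

## The problem

Head motion degrades structural MRI. In group studies the usual remedies are
binary: keep an image or discard it. But motion acts on a continuum — a
slightly degraded map still carries signal, just with more noise. Treating
all images as equally noisy (ordinary least squares, OLS) violates the
homoscedasticity assumption of the voxel-wise general linear model (GLM):
parameter precision is misestimated and test statistics lose their nominal
behaviour.

quiqir implements the alternative: convert a per-image quality index into a
per-image noise *variance*, and run the mass-univariate GLM as weighted
least squares (WLS). Degraded images are down-weighted in proportion to
their estimated noise, never discarded.

## The quality index

The motion degradation index (MDI) used here is the standard deviation of
R2\* within white matter. R2\* (the effective transverse relaxation rate,
s^-1^) is estimated per voxel from multi-echo gradient-echo magnitude data
by ordinary least squares on the log signal — for a mono-exponential decay
$S(TE) = S_0 e^{-R_2^* TE}$ the log-signal slope against echo time is
$-R_2^*$. White matter has sharp, relatively uniform R2\* contrast; motion
blurs it, inflating its spatial spread, which makes the within-mask
standard deviation a sensitive per-image quality score. The package
implements the literal definition (sample SD, divisor $n-1$); probabilistic
masks are binarised at 0.5 by default. Voxels with any non-positive echo
signal are excluded rather than clipped so the log-linear model stays exact.

## The noise model

Let $y_n \in \mathbb{R}^N$ hold the values of voxel $n$ across the $N$
subjects, $X$ the design matrix (intercept, age, age^2^, sex, brain
volume by default). The model is

$$y_n = X\beta_n + \varepsilon_n, \qquad
\varepsilon_n \sim \mathcal{N}(0, V), \qquad
V = \sum_i \lambda_i Q_i, \qquad Q_i = \mathrm{diag}(\mathrm{MDI}^{\alpha_i}).$$

$V$ is diagonal (noise is independent between subjects) and shared by all
voxels in the analysis pool; it is estimated once per pool, never per voxel.
The basis powers $\alpha_i$ are user-chosen; $\alpha = 0$ contributes the
homoscedastic (thermal) noise floor and a cubic term is typically the
dominant motion component for R2\* maps.

The hyperparameters $\lambda$ are estimated by restricted maximum
likelihood (REML), maximising the evidence lower bound (ELBO; equivalently
the negative variational free energy), which up to a constant is

$$E(\lambda) = -\tfrac{N_v}{2}\ln|V|
  - \tfrac{N_v}{2}\ln|X^\top V^{-1} X|
  - \tfrac{1}{2}\sum_{n=1}^{N_v}
  (y_n - X\hat\beta_n)^\top V^{-1} (y_n - X\hat\beta_n),$$

with $N_v$ the number of voxels and $\hat\beta_n$ the generalised
least-squares estimates. The pooled second-moment matrix
$S = YY^\top/N_v$ is the sufficient statistic, so the cost per iteration is
independent of the voxel count once $S$ is formed. From the converged $V$,
the analysis weights are $W = V^{-1/2}$, and the WLS fit is OLS on the
whitened pair $(WY, WX)$.

A note on the middle term: the standard restricted likelihood carries
$\ln|X^\top V^{-1} X|$. `elbo(..., form = "printed")` evaluates the variant
with $\ln|X^\top V X|$ instead, retained purely for audit; the default and
every analysis in the package use the standard form.

### Optimisation and numerical choices

* Fisher scoring on $\lambda$, or on $\log\lambda$ when positivity is
  enforced (the default, mirroring the positivity-constrained estimation
  the method was validated with; the unconstrained variant is a flag).
* Steps are halved whenever a proposed update would lower the ELBO or make
  $V$ lose positive definiteness, so the accepted trace is non-decreasing.
* Initial $\lambda$ splits the pooled OLS residual variance equally across
  components, each scaled by its mean basis diagonal.
* Convergence: relative ELBO change below `tol = 1e-8` (scoring is
  quadratically convergent near the optimum, so this costs only a handful
  of iterations and pins the hyperparameters to well beyond diagnostic
  accuracy), with `max_iter = 128` and a flagged warning on
  non-convergence.
* The MDI vector is rescaled to unit mean before powering. This conditions
  the hyperparameter scales; it rescales $\lambda_i$ by
  $\mathrm{mean}(\mathrm{MDI})^{\alpha_i}$ and leaves $V$, $W$, $\hat\beta$,
  F statistics and model ranking unchanged. Estimates are reported back on
  the original MDI scale.
* A singular $X^\top V^{-1}X$ is reported as a design-deficiency error.

### Model selection

Candidate basis sets are compared by their converged ELBO. The restricted
likelihood itself penalises complexity: basis functions the data do not
support are driven to the positivity boundary and contribute nothing, so a
superset of the generating basis gains no material evidence over it. The
gain over the homoscedastic basis $\{0\}$ (the OLS assumption) is reported
per candidate, and `regional_elbo()` repeats the selection within regions
of any integer label image (regions under 50 voxels are skipped).

## Inference

* **F tests** of a design-column subset use the extra-sum-of-squares
  statistic on the whitened fit; a single-column contrast reduces to the
  squared t statistic. Two-sample comparisons with covariates are a t test
  on the group coefficient.
* **Voxel-level familywise error** is controlled by Bonferroni
  ($p \le \alpha/N_\text{voxels}$). This replaces random-field-theory
  correction deliberately: it is assumption-free, exact under independence
  and conservative otherwise, and behaves predictably at the problem sizes
  the package targets.
* **Cluster-level inference** thresholds the map at an uncorrected
  cluster-forming p (default 0.001), labels 26-connected components
  (6-connectivity switchable) and assigns familywise p-values from the
  permutation null of the maximum cluster extent. Permutation follows
  Freedman–Lane: residuals of the reduced model are permuted and added back
  to the reduced-model fit, which respects nuisance covariates.
* WLS error degrees of freedom are $N - \mathrm{rank}(X)$, treating the
  estimated $\lambda$ as fixed — the standard practice in this framework;
  the uncertainty in $\lambda$ is ignored and said so here.

## Diagnostics

Two complementary heteroscedasticity measures:

* **Global**: each subject's residual map is summarised by its spatial
  variance $\mathrm{var}[\varepsilon]$; an order-3 polynomial of the MDI is
  fitted to these values and the fraction of variance explained ($R^2$) is
  the heteroscedasticity score. Near 0 means homoscedastic; OLS on
  motion-degraded cohorts typically scores far higher. The polynomial
  coefficients are unconstrained in sign, and $R^2$ is defined as 0 when
  the noise estimates have no spread.
* **Voxel-wise**: Engle's ARCH Lagrange-multiplier test is applied to each
  voxel's residual series *ordered by ascending MDI* (the ordering is a
  package choice — the source analyses do not state one; ordering by MDI
  makes MDI-dependent variance manifest as the volatility clustering the
  test detects; input-order and random orderings are available for
  sensitivity checks). Squared residuals are regressed on 40 of their own
  lags, $LM = nR^2_{aux}$ is referred to $\chi^2(40)$, and the fraction of
  voxels significant after Benjamini–Hochberg FDR correction is reported,
  alongside Kolmogorov–Smirnov normality checks.

Two diagnostic subtleties worth stating plainly:

* **Leverage.** A residual map's raw spatial variance is
  $(1-h_{jj})$ times the subject's noise variance. In weighted fits the
  leverage $h_{jj}$ concentrates on the *least* noisy images, so at cohort
  sizes where $p/N$ is not negligible the uncorrected variances acquire a
  spurious dependence on the MDI. `residual_spatial_variance()` therefore
  studentizes by $\sqrt{1-h_{jj}}$ by default (`leverage_correct = FALSE`
  recovers the raw variant). At very large $N$ the two coincide.
* **ARCH finite-sample behaviour.** The $\chi^2(40)$ reference requires the
  series to be long relative to the 41-parameter auxiliary regression; the
  test is anti-conservative around $N \approx 200$ and approximately
  calibrated from several hundred subjects upward. Diagnostics on cohorts
  smaller than `max_lag + 3` report `NA`.

On WLS fits all diagnostics use the whitened residuals — the quantity the
noise model claims is homoscedastic. This is an interpretive choice; raw
residuals can always be inspected via an unweighted fit.

## The synthetic cohort generator

`generate_cohort()` draws the data-generating process the method assumes,
so parameter recovery, calibration and power can be tested end to end
without any imaging data:

* MDI from an offset gamma, `shape 2, scale 1, offset 0.5` (s^-1^): a
  strictly positive, right-skewed distribution of the kind quality indices
  show empirically; the family is configurable, the offset keeps negative
  basis powers usable.
* Covariates: age uniform on 20–80 y (narrow strata, e.g. 56–58 y, emulate
  the zero-age-effect subcohorts used in specificity analyses), sex
  Bernoulli(0.5), brain volume normal (1400 ± 130 ml). The design matrix
  centres age and its square, which conditions the design without touching
  joint F tests of the age columns.
* Noise: independent Gaussians with
  $\mathrm{Var}(\varepsilon_j) = \sum_i \lambda_i \mathrm{MDI}_j^{\alpha_i}$;
  the default study conditions elsewhere in the package are the unit floor
  plus cubic term ($\lambda = (1, 0.05)$, $\alpha = (0, 3)$) or the purely
  cubic $\lambda = 0.05$, $\alpha = 3$. Optional Gaussian smoothing of the
  noise field (grid cohorts) adds spatial correlation, with per-subject
  variances renormalised afterwards.
* True age effects: a configurable fraction of active voxels with slopes in
  units of map value per year (default 0.02, about 1.5 standard deviations
  of typical-noise signal per age SD at the default conditions;
  heterogeneous slopes via a range).
* Multi-echo series: $S_0 e^{-R_2^* TE}$ plus Gaussian or Rician noise, for
  exercising the R2\* fit.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: anatomical structure and partial-volume
mixing, spatially varying (non-MDI) noise mechanisms such as field
inhomogeneity, registration and segmentation error, non-Gaussian artefact
tails, and any dependence between the MDI and the covariates (in ageing
cohorts motion correlates with age; the generator draws them
independently). The synthetic checks validate the estimator and its
calibration under the model's own assumptions, not the assumptions
themselves.

## Experiment harnesses and study conditions

The package ships the validation harnesses as first-class functions:
scrambled-age specificity (`specificity_scramble()`, with the
up-to-10-per-5-year age-bin subsampling rule available), null two-sample
comparisons at configurable group imbalance, exclusion-threshold analysis
(drop the `ceiling(f N)` highest-MDI images, ties broken by subject order),
MDI-as-covariate comparison (mean-centred MDI^1..4^ as regressors), and
regional model selection. Every harness derives all randomness from an
integer seed; replicate $r$ uses `seed + r`, so extending a run reproduces
its prefix exactly.

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's standard conditions: cohorts of 100–300 subjects
(1432 only for the large-cohort ARCH contrast), 500–5000 voxels,
500–5000 scrambling replicates. One sizing note: with 500 independent
voxels the exact-null Bonferroni familywise rate is
$1-(1-10^{-4})^{500} = 0.0488$, so the scrambling harness reports are run
at 5000 replicates, where Monte-Carlo error (SE ≈ 0.003) no longer
dominates the distance to the 0.05 bound.

Two harness-design choices were genuinely open and are fixed as follows:
age and age^2^ are permuted *jointly* (the pair must stay consistent for
the permuted design to mean anything), and the specificity null cohorts
pair the floor-plus-cubic variance with the basis $\{0, 3\}$ — a noise
model must be able to represent the homoscedastic floor of the data it
whitens; feeding the cubic basis alone to data with a unit floor
mis-weights the cleanest images by orders of magnitude and invalidates the
test it is meant to calibrate.

## Limitations

* Diagonal $V$ only: between-subject correlation and voxel-specific
  hyperparameters are out of scope.
* $\lambda$ is treated as known at inference time; no Kenward–Roger-style
  dof correction is attempted.
* Bonferroni voxel-level control is conservative under strong spatial
  correlation; cluster-level permutation is exact under exchangeability but
  costs replicates.
* The R2\* fit is plain log-linear OLS: no noise-floor weighting, no
  multi-contrast pooling, no RF/B1 corrections, and no segmentation or
  spatial normalisation — maps and masks are expected in a common space.
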