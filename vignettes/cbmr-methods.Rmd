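---
title: "Spatial meta-regression of activation foci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial meta-regression of activation foci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Coordinate-based meta-analysis (CBMA) pools neuroimaging studies that report
only the x, y, z peak coordinates of activation ("foci"). `cbmr` estimates a
smooth activation intensity over the brain from such data with a generative
meta-regression: the per-(study, voxel) focus count $Y_{ij}$ has expectation

$$\log \mu_{ij} \;=\; x_j^\top\beta \;+\; Z_i\gamma,$$

where $x_j^\top$ is row $j$ of an $N\times P$ spatial design matrix of
tensor-product cubic B-splines, $\beta$ are the spline coefficients, and
$Z_i$ holds optional mean-zero study-level covariates with global effects
$\gamma$. The intensity factorizes as
$\mu_{ij}=\mu^X_j\mu^Z_i$ with $\mu^X=\exp(X\beta)$ and
$\mu^Z=\exp(Z\gamma)$. Centering every covariate is what makes the
decomposition identifiable: the spatial part carries the overall level.

## Spatial basis

Each axis gets a 1D cubic B-spline basis with equally spaced knots
(`spacing_mm`, default 20 mm); the volume basis is the tensor product of the
three axis bases. Knots are anchored at integer multiples of the spacing in
mm coordinates and extended past both ends of the axis by `degree` extra
equally spaced knots, so the basis is uniform (not clamped) and partitions
unity at every voxel centre. The anchoring rule is deterministic and isolated
in `knot_config()`, so alternative origins can be explored without touching
the assembly code.

The design matrix is reduced in three steps: rows outside the brain mask are
dropped; columns whose maximum in-mask coefficient is below
`support_threshold` (default 0.1, strict inequality) are pruned as weakly
supported; remaining rows are renormalized to sum to one, restoring the
partition of unity. A practical bound worth knowing: the largest value a
tensor cubic B-spline coefficient can attain is $(2/3)^3 \approx 0.296$, so
thresholds at or above that prune everything and raise a basis-coverage
error. The full-lattice coefficient matrix is never materialized; rows are
assembled sparsely for in-mask voxels only (at most $4^3 = 64$ nonzeros per
row), which is what makes a 200,000-voxel analysis tractable in memory.

## Stochastic models

Four models for the counts, all consuming only the sufficient statistics
$Y_{\cdot,j}$ (per-voxel sums over studies), $Y_{i,\cdot}$ (per-study sums),
$M$ and $N$ — never the $M\times N$ data matrix. Because two reported peaks
of one study land in the same voxel only through coordinate rounding (and
preprocessing clamps such duplicates), per-(study, voxel) counts are 0/1 and
all $\log Y_{ij}!$ terms vanish.

* **Poisson.** Complete log-likelihood
  $Y_{\cdot,}^\top\log\mu^X + Y_{,\cdot}^\top\log\mu^Z -
  (\mathbf 1^\top\mu^X)(\mathbf 1^\top\mu^Z)$.
* **Negative Binomial (NB).** Each $Y_{ij}$ is NB with mean $\mu_{ij}$ and
  variance $\mu_{ij}+\alpha\mu_{ij}^2$, one dispersion $\alpha$ for the whole
  analysis. A sum of NB variates is not NB, so the per-voxel sum is
  approximated by the NB matching its exact first two moments. The study
  factor cancels, leaving a voxel-constant size
  $r = s_1^2/(\alpha s_2)$ and
  $p_j = \mu^X_j s_2 / (s_1/\alpha + \mu^X_j s_2)$, with
  $s_1=\sum_i\mu^Z_i$, $s_2=\sum_i(\mu^Z_i)^2$ and effective dispersion
  $\alpha' = \alpha s_2/s_1^2$.
* **Clustered NB.** One latent Gamma$(1/\alpha, 1/\alpha)$ multiplier per
  study scales that study's entire intensity, inducing within-study
  covariance $\alpha\mu_{ij}\mu_{ij'}$. With 0/1 counts the marginal
  log-likelihood reduces exactly to the per-study sums, so it is computed
  on sufficient statistics despite the shared latent variable.
* **Quasi-Poisson.** Mean model plus variance $\theta\mu$ ($\theta\ge 1$);
  no likelihood, fitted by IRLS with $\theta$ profiled out afterwards via
  the Pearson statistic over voxels divided by $N-P$.

### Constant conventions and model comparison

The Poisson and clustered-NB objectives are complete log-likelihoods on the
per-(study, voxel) data scale; the NB objective models the per-voxel *sums*.
The two scales differ by $\sum_j\log Y_{\cdot,j}!$ *and* by the
study-allocation term $\sum_i Y_{i,\cdot}\log\mu^Z_i - Y_{\cdot\cdot}\log
s_1$ (the information about which study produced each focus, which the
summed representation discards). `lrt()` therefore compares Poisson against
NB by re-expressing the Poisson fit on the summed-count scale — the Poisson
MLE maximizes that objective too, since it is a function of the fitted mean
vector only — and compares Poisson against clustered NB directly.
`model_aic()` exposes both conventions via its `scale` argument. The null
value $\alpha=0$ sits on the boundary of the parameter space; the plain
one-degree chi-squared reference is used as is, which is conservative.

## Fitting

* Covariate-free Poisson: Fisher scoring with the closed-form score and
  information ($X^\top\mathrm{diag}(\mu^X)X$ blocks), with step-halving so
  the objective never decreases.
* Everything else likelihood-based: L-BFGS-B over
  $(\beta, \gamma, \log\alpha)$. Dispersion is optimized on the log scale to
  enforce positivity, box-bounded in $[-20, 10]$; at the lower bound the NB
  families are numerically Poisson and the fit is annotated. Scores are
  analytic for $\beta$ and $\log\alpha$ in every family (central finite
  differences cover only the short $\gamma$ block of the NB family).
* Quasi-Poisson: IRLS on the sufficient statistics. The printed update for
  the study block has no intercept, but $E[Y_{i,\cdot}]$ carries an overall
  scale that mean-zero covariates cannot absorb, so the implementation
  augments the study-block design with an internal intercept (discarded
  afterwards) and shifts the reported $\beta$ by $-\log s_1$; with centered
  covariates this reproduces the joint quasi-score solution, and at
  $\theta=1$ the estimates match the Poisson fit.

Initialization is deterministic and scale-aware: $\beta$ starts at the
constant field matching the observed mean rate
($\log(\text{total}/(MN))$, which the row-stochastic basis maps to a flat
log-intensity), $\gamma$ and $\log\alpha$ at zero. Convergence requires a
relative objective change below `tol` (default 1e-8) and a max absolute
score below `grad_tol` scaled by $1+|\ell|$ — an absolute gradient cutoff is
meaningless across data sizes. When the optimizer halts on a flat objective
with a code other than clean convergence, the iterate is accepted only if
the realized score passes that same test (a bound-active $\log\alpha$ row is
exempt).

The observed information at the optimum is recomputed — closed form for
Poisson, symmetric central differences of the analytic gradient otherwise
(step $\varepsilon^{1/3}(1+|\hat\theta_k|)$) — never taken from the
optimizer's internal approximation.

A numerical note: as $\alpha\to 0$ the matched NB size $r$ diverges and
$\log\Gamma(y+r)-\log\Gamma(r)$ loses precision to cancellation; for
$r>10^8$ it is evaluated as $\sum_{k=0}^{y-1}\log(r+k)$ (counts are small
integers), keeping the Poisson limit clean. No regularization is applied
anywhere: coefficients diverging toward $-\infty$ in zero-foci regions are
reported, not clipped (beyond a $\pm300$ overflow guard on linear
predictors, which is logged).

## Inference

The spatial homogeneity test asks, voxel by voxel, whether the spatial
intensity exceeds the global mean rate $\mu_0 = \sum Y_{ij}/(MN)$:
$Z = (\hat\eta^X_j - \log\mu_0)/\mathrm{SE}(\hat\eta^X_j)$ with
$\mathrm{Var}(\hat\eta^X_j) = x_j^\top I^{-1}_{\beta\beta}x_j$ from the
inverse observed information, and
$\mathrm{SE}(\hat\mu^X_j)=\hat\mu^X_j\,\mathrm{SE}(\hat\eta^X_j)$ by the
delta method. The test targets the spatial component only; covariates enter
through the fit, not the tested quantity. P-values are two-sided by default
(the Z maps are signed; a one-sided option serves activation-only
inference).

Low-foci datasets can drive coefficients toward $-\infty$ and the
information toward singularity. The inverse is then taken on the
well-determined eigen-subspace and voxels whose basis row loads on the null
space get `NaN` standard errors and are excluded from FDR accounting — a
pseudo-inverse that silently deflates variances would inflate significance,
which is exactly the failure mode the truncation below guards against.

Asymptotic Wald p-values are reliable near conventional levels but can skew
liberal in the extreme tail. Before Benjamini-Hochberg FDR control at 5%,
p-values are floored at $10^{-3}$ (`truncate_p`); rejection then requires at
least $q^{-1}\,10^{-3}\,N \approx 0.02\,N$ voxels at the floor
simultaneously, which a homogeneous null essentially never produces. This
costs power only where more than ~2% of the brain is at the floor.

Covariate effects are tested with general linear hypothesis contrasts
$C\gamma=0$ via the asymptotic chi-squared Wald statistic (signed z for a
single contrast). Goodness of fit across families is summarized by AIC/LRT
plus three relative-bias metrics: total fitted intensity against the focus
count; per-axis SD of the fitted intensity's marginal coordinate
distribution against the empirical foci-coordinate SD; and, over voxels with
at least one focus, the family's model variance against the mean squared
residual over studies (the latter needs the per-study incidence matrix,
which `foci_to_counts()` retains).

## The synthetic-data generators

`sample_model_based_null()` emulates a homogeneous null matched to a
published dataset's size: per-study focus counts Poisson with the stated
mean (a fixed-totals mode exists), locations uniform over in-mask voxel
centres, within-study duplicates clamped exactly as in preprocessing.
`shuffle_empirical_null()` keeps each study's count and resamples locations
without replacement. `sample_structured()` draws from the fitted families'
generative processes (including the per-study Gamma hierarchy) and clamps
counts to 0/1, warning when the clamp rate exceeds 5%.

What these generators do *not* emulate: spatially clustered foci within
studies, anatomically realistic masks, coordinate-space conversion error,
and reporting biases. Passing calibration on them therefore demonstrates
correctness of the estimator and the inference chain under the stated
models, not robustness to every property of real meta-analytic data.

The default simulation space is a 30×30×30 lattice of 2 mm voxels with an
ellipsoid mask of semi-axes 24×26×22 mm ($N = 7216$ voxels) and 12 mm knot
spacing ($P = 85$ bases) — proportions chosen so the basis-per-voxel ratio
resembles a full-brain analysis at 20 mm spacing while a complete NB fit
runs in about two seconds. Null calibration experiments
(`run_null_experiment()`) at the largest published configuration (M = 275
studies, 11.63 foci/study) use 20–40 realizations; each derives its RNG
stream deterministically from the experiment seed, and non-converged
realizations are counted and excluded, never silently dropped.

## Design choices where the design was open

* **Coordinate rounding:** nearest lattice position, ties away from zero;
  foci are included iff their rounded voxel is in-mask. No Talairach
  conversion — inputs are assumed already in the mask's space.
* **Study identity:** covariate rows are matched by study id, never by row
  order; each contrast of a publication is treated as an independent study.
* **Dispersion identifiability:** with $M$ studies and no covariates the
  NB effective dispersion is $\alpha/M$, so on homogeneous nulls with small
  per-voxel rates $\hat\alpha$ is weakly identified and may wander at no
  cost to the fit or the inference maps (the implied variance inflation is
  $O(\alpha\bar\mu^X)$). Voxel-level $\alpha$ recovery is only a meaningful
  check in regimes where $\alpha\,\mu_{\cdot,j}/M$ is appreciable; the test
  suite exercises exactly that regime, and uses the clustered family (whose
  study-level dispersion is strongly identified) for recovery at realistic
  rates.
* **Clustered-NB optimizer:** quasi-Newton by default; Fisher scoring is
  exposed for the covariate-free Poisson only.
* **Moment-matching accuracy:** exact in first and second moments for any
  mix of study effects; the pmf approximation error is negligible at small
  $\alpha'$ and grows with dispersion — at extreme dispersion
  ($\alpha\,\mu M^{-1}\sim 0.5$) recovery simulations show a mild downward
  bias in $\hat\alpha$, documented in the tests.

## Limitations

Single study group; global (not spatially varying) covariate effects; no
zero-inflation; no roughness penalty (smoothness is controlled by knot
spacing alone); asymptotic tests without small-sample corrections; FDR but
no FWER control. P-values below the truncation floor are reported as the
floor, by design.
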