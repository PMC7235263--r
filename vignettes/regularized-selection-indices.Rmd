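---
title: "Regularized selection indices: models, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized selection indices: models, estimation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psindex)
```

## The problem

High-throughput phenotyping produces hundreds of secondary phenotypes per
plot — here the motivating case is hyper-spectral reflectance, with
`p = 250` wavebands between 392 and 850 nm measured on wheat yield-trial
plots. A selection index (SI) predicts the *genetic merit* of a target trait
(grain yield) from these measured traits:

$$ I_i = \mathbf{x}_i'\boldsymbol\beta, $$

with weights chosen to minimize the expected squared deviation between the
index and the genetic merit $g_{y_i}$. When the phenotypic covariance matrix
$\mathbf{P}_x$ of the bands and the vector $\mathbf{G}_{xy}$ of genetic
covariances between bands and target are known, the solution is the classical

$$ \boldsymbol\beta = \mathbf{P}_x^{-1}\mathbf{G}_{xy}, $$

which is the best linear predictor (BLP) of $g_y$. With hundreds of bands and
a few hundred training plots, however, the *estimated* $\hat{\mathbf{P}}_x$
and $\hat{\mathbf{G}}_{xy}$ carry enough error that the plug-in standard SI
overfits: its heritability collapses and the accuracy of indirect selection
drops. This package implements regularized alternatives:

* **L2-PSI** (ridge type): $\boldsymbol\beta_{L2} = (\mathbf{P}_x + \lambda
  \mathbf{I})^{-1}\mathbf{G}_{xy}$, computed in closed form
  (`l2_psi()`).
* **L1-/EN-PSI** (sparse): minimizers of
  $-\mathbf{G}_{xy}'\boldsymbol\beta + \tfrac12\boldsymbol\beta'\mathbf{P}_x
  \boldsymbol\beta + \lambda J(\boldsymbol\beta)$ with
  $J = \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
  \alpha\lVert\beta\rVert_1$, solved by covariance-form cyclical coordinate
  descent (`en_psi()`) and, for $\alpha = 1$, by a covariance-updates LARS
  path algorithm with the lasso modification (`lars_psi()`). No data matrix
  is touched: $\mathbf{P}_x$ and $\mathbf{G}_{xy}$ enter exactly where
  $\mathbf{X}'\mathbf{X}$ and $\mathbf{X}'\mathbf{y}$ would in a phenotypic
  elastic net.
* **PC-SI** (reduced rank): with $\mathbf{X} = \mathbf{U}\mathbf{D}
  \mathbf{V}'$ and scores $\mathbf{W} = \mathbf{XV}$, the method-of-moments
  covariance of the first $q$ scores is $\tilde{\mathbf{D}}^2/(n-1)$, so the
  score coefficients are $(n-1)\tilde{\mathbf{D}}^{-2}
  \mathbf{G}_{\tilde w y}$ and map back to band space through
  $\tilde{\mathbf{V}}$ (`spectral()`, `pc_si()`). $q = p$ reproduces the
  standard SI.

The front end `psi()` dispatches on `method` and returns a classed object
with `coef`, `predict`, `print`, `summary` and `plot` methods.

## Pre-processing and genetic parameters

Plot records are pre-adjusted within environment by the all-random-effects
model

$$ y_{jklm} = \mu + g_j + t_k + r_{l(k)} + b_{m(kl)} + \varepsilon_{jklm}, $$

(genotype, trial, replicate within trial, sub-block within replicate) fitted
by REML through `lme4::lmer()` (`fit_random_model()`). The adjusted record
subtracts the mean and the *nuisance* BLUPs only, so
$y^* = \hat g_j + \hat\varepsilon$ keeps the genetic signal
(`preadjust()`; bands add an optional crossed time-point effect and are
adjusted one model per band, `preadjust_bands()`). Adjusted target records
outside $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$ are dropped
(reflectance rows of the same plots are dropped in tandem) and the survivors
are scaled to unit variance (`filter_standardize()`).

After adjustment, all genetic parameters come from the univariate
one-factor model $y_{ij} = \mu + g_j + \varepsilon_{ij}$:
plot-basis heritability $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$
(`heritability()`), and genetic covariances by the sum-of-traits identity

$$ \hat G_{y,x} = \tfrac12\left(\hat\sigma^2_{g,y+x} - \hat\sigma^2_{g,y}
   - \hat\sigma^2_{g,x}\right) $$

(`gen_covariance()`, and `gen_covariance_panel()` for a whole band panel).
Because this model is fitted once per band, per trait sum, and per training
partition, the package implements it as a profiled REML: with
$\phi = \sigma^2_g/\sigma^2_e$ the restricted likelihood reduces to a 1-D
criterion over group sufficient statistics, whose optimum is located by a
sign change of its analytic derivative (log-grid scan plus 90 bisection
steps). This is exact, deterministic, equivariant under exact rescalings of
the response (which makes the self-covariance and bilinearity identities of
the sum trick hold to near machine precision), and roughly three orders of
magnitude faster than a general mixed-model fitter on these problems; it is
cross-checked against `lme4` and against the balanced-ANOVA closed form in
the test suite. Variance estimates at the boundary are reported as exactly
zero; heritabilities are clipped to $[0,1]$; genetic covariances built from
clipped components are retained as-is, so estimated genetic correlations can
leave $[-1,1]$ and are then clipped with a logged count.

## Evaluation: accuracy of indirect selection

Accuracy must be estimated on data not used to derive the coefficients, so
evaluation blocks by *trial*: complete trials are assigned to training or
testing (`make_partitions()`, default two-thirds training). On testing plots,
`evaluate_index()` estimates $h^2_I$, $h^2_y$ and the genetic correlation
$r_g = \hat G_{I,y}/\sqrt{\hat\sigma^2_{g,I}\hat\sigma^2_{g,y}}$, and reports

$$ \mathrm{Acc}(I) = h_I\, r_g, \qquad
   \mathrm{RE} = \frac{h_I}{h_y} r_g, $$

where $h_I = \sqrt{h^2_I}$ — the *square root* scale is the only one on
which these two formulas cohere, and is adopted throughout.
`tune_si()` runs this machinery over a complexity grid (penalty $\lambda$
for L1/EN/L2, number of components $q$ for PC), aggregates mean and SD of
accuracy across partitions, picks the grid point with maximal mean accuracy
(ties broken toward the least complex solution), and refits it on the full
data. `summarize_partitions()` reports normal-approximation 95% confidence
intervals for partition means. Baselines: `vegetation_index()` (RNDVI/GNDVI
with configurable windows, defaults Red 660–680 nm, Green 540–560 nm, NIR
780–850 nm — standard definitions inside the 392–850 nm camera range) and
`l1_phen()`, the same solver fed phenotypic covariances
$\mathbf{X}'\mathbf{y}/(n-1)$ instead of genetic ones.

### Leakage control

Band centering/scaling, $\hat{\mathbf{P}}_x$, $\hat{\mathbf{G}}_{xy}$ and
the SVD are always computed on training plots only and applied unchanged to
testing plots. Inside `tune_si()` the band panel is standardized within the
training set rather than BLUP-adjusted band by band; the generator's band
nuisance effects are iid across bands, so they inflate band variances
without creating spurious band–band or band–target covariance. For
fixed-coefficient evaluation studies the package also exposes full per-band
mixed-model adjustment (`preadjust_bands()`), which is what the
accuracy-consistency analyses use.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` grid | 100 points, log-spaced, $\lambda_{max} = \max_j\lvert G_j\rvert / \max(\alpha, 10^{-3})$ down to $10^{-4}\lambda_{max}$ | penalty strength; at $\lambda \ge \lambda_{max}$ the L1 solution is exactly zero |
| `alpha` | 1 | elastic-net mix; 1 = LASSO, 0 = ridge |
| `q` | tuned | number of principal components |
| CD `tol`, `maxit` | $10^{-9}$, 10 000 | largest absolute coefficient change per sweep; sweeps per $\lambda$ |
| `fence` | 3 | IQR multiplier of the outlier fence (type-7 quantiles) |
| NDVI windows | Red 660–680, Green 540–560, NIR 780–850 nm | configurable wavelength windows |

Inside `tune_si()` the default grid is shortened (30 points down to
$10^{-2}\lambda_{max}$): accuracy curves are flat at that resolution and the
dense tail of the path — where the active set approaches the sample rank and
coordinate descent converges slowly — contributes nothing to tuning.

## Numerical choices

* Coordinate descent cycles in band order and uses the usual active-set
  strategy (full sweeps establish the active set, inner sweeps iterate it to
  convergence); warm starts along the decreasing grid. Convergence is
  declared when the largest absolute coefficient change in a sweep falls
  below `tol`; non-convergence is flagged, never silent.
* Every L1/EN solution can be certified independently of the solver through
  its Karush–Kuhn–Tucker conditions (`kkt_violation()`); the test suite uses
  this as the primary correctness oracle, plus a brute-force enumeration
  solver at small `p`.
* LARS breaks exact ties at entry events toward the lowest band index
  (simultaneous boundary crossings enter together) and handles drop events
  per the lasso modification; a band dropped at a knot may not re-enter at
  the same knot. Tie events are counted in attribute `"ties"`.
* `standard_si()` refuses covariance matrices with reciprocal condition
  number below $10^{-12}$ rather than silently pseudo-inverting; the error
  suggests the regularized families.
* The IQR fence uses linear-interpolation (type 7) quantiles; the fence is
  "quartile $\pm$ 3 IQR". Both are fixed conventions, stated here because
  reasonable alternatives exist.
* `sim_truth()` builds band-level genetic covariance as a low-rank smooth
  factor structure and environmental covariance as a Gaussian-kernel
  correlation with an independent `nugget` (default 0.05) — the nugget
  represents per-band sensor noise and keeps population covariances
  well-conditioned.

## What the generator emulates — and what it does not

`sim_truth()`/`sim_trials()` emulate the structure of multi-environment
phenotyping trials: genotypes nested in trials, alpha-lattice style
replicates and sub-blocks with iid nuisance effects, smooth band-to-band
correlation decaying with wavelength distance, a low-dimensional genetic
factor space shared by bands and target, and environmental band deviations
orthogonal to the target's genetic merit (the assumption under which the SI
is the BLP). Defaults mirror the motivating design: 39 trials × 28
genotypes × 3 replicates × 6 sub-blocks, band heritability 0.5, trial/
replicate/sub-block variances 0.2/0.05/0.05 on a unit phenotypic scale.
A requested band–target genetic-correlation profile is projected onto the
genetic factor space; infeasible profiles (implying more explained genetic
variance than the target owns) raise an error rather than being silently
shrunk. The joint band+target genetic covariance is PSD by construction.

Real reflectance data have features the generator does not attempt:
time-point-specific spectral signatures, heteroscedastic and skewed band
distributions, spatial field trend, genotype-by-environment interaction,
and pedigree relatedness among lines. Tests passing on synthetic data
therefore validate the estimators and solvers under the stated generative
assumptions — they do not certify performance on any particular real crop
dataset.

One finite-design subtlety: because genotypes are nested in trials, the
trial BLUP absorbs a fraction $\approx 1/m$ (with $m$ genotypes per trial)
of the genetic variance during pre-adjustment, so empirical accuracies sit
very slightly below the closed-form population value; with the default
$m = 28$ this is well inside Monte-Carlo noise at the problem sizes used.

## Problem sizes used in the shipped analyses

The test suite and `scripts/acceptance.R` run three synthetic studies,
sized to be informative while keeping a full run on one CPU comfortable:
parameter recovery uses 200 Monte-Carlo draws of a 500-genotype × 3-replicate
balanced design; estimator-consistency uses datasets of 21 trials × 28
genotypes × 3 replicates with 200 trial-blocked partitions spread over
independent datasets; the regularization study uses `p = 250` bands, a
rank-8 genetic structure, 30 trials × 10 genotypes × 2 replicates
(≈ 400 training plots per partition) with 100 seeded replicates in the test
suite and 30 in the acceptance script.

## Known limitations

* Univariate REML plus the sum trick only: no multivariate REML, no
  pedigree or genomic relationship matrices, no spatial trend correction.
* The one-step index for borrowing information across individuals
  (Kronecker-structured genetic covariances) is out of scope.
* `tune_si()` tunes by indirect-selection accuracy, not by phenotypic
  prediction error; cross-validation of $\lambda$ against phenotypes is
  deliberately absent.
* Significance testing of accuracy differences between index families
  (e.g. multiple-comparison procedures) is not provided.

## A minimal worked session

```{r, eval = FALSE}
truth <- sim_truth(p = 50, n_factors = 5, decay = 0.08,
                   r_g_profile = 0.45 * exp(-((1:50 - 12) / 8)^2))
sim <- sim_trials(truth, n_trials = 20, genotypes_per_trial = 28,
                  replicates = 3, seed = 1)
fs <- filter_standardize(preadjust(sim$pheno))
keep <- fs$retained
parts <- make_partitions(sim$pheno$trial[keep], n_partitions = 10, seed = 2)
tuned <- tune_si(fs$values[keep], sim$bands[keep, ],
                 sim$pheno$genotype[keep], sim$pheno$trial[keep],
                 method = "L1", partitions = parts)
print(tuned)
plot(tuned)
true_accuracy(tuned$optimal, truth)
```
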