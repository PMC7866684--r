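---
title: "Coupled mixed models for joint GWAS analysis: model, solver, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled mixed models for joint GWAS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledmm)
```

## The problem

Two GWAS cohorts are collected independently, each for its own disease:
cohort 1 measures phenotype 1 only, cohort 2 measures phenotype 2 only,
and both are genotyped on (an intersection of) the same SNP panel. The
scientific question is which SNPs are associated with *both* phenotypes.
Summary-statistic methods exist for this, but individual-level data
carries more information — in particular the genotype distribution
itself, which lets us estimate and correct two confounder classes that
plague naive joint analyses:

* **population-structure confounding** — stratification, family
  structure and cryptic relatedness, captured by a random effect
  `u ~ N(0, sigma_u^2 K)` spread along the kinship matrix
  `K = X X' / p`; its variance is *phenotype*-specific;
* **collection (batch) confounding** — artifacts of each cohort's
  collection procedure, captured by an iid random effect
  `v ~ N(0, sigma_v^2 I)` whose variance is *cohort*-specific.

The generative model writes, for cohort $i$ and phenotype $j$,

$$ y_i^{(j)} = X_i \beta^{(j)} + u_i^{(j)} + v_i + \epsilon_i^{(j)}, $$

of which only $y_1^{(1)}$ and $y_2^{(2)}$ are observed. The iid residual
$\epsilon$ is dropped during estimation: once $v_i$ is in the model an
extra iid term is unidentifiable, so the iid variance of each cohort's
null covariance is attributed entirely to $\sigma_{v_i}^2$.

## The coupled estimator

Writing the joint negative log-likelihood after replacing the
unobserved cross-phenotypes with their model predictions
($y_1^{(2)} \to X_1\beta^{(2)}$, $y_2^{(1)} \to X_2\beta^{(1)}$), and
putting Laplace priors on the coefficients, the estimator minimizes

$$ \frac{\hat\sigma_{22}}{2t}\,\lVert y_1^{(1)} - X_1\beta^{(1)}\rVert_2^2
 + \frac{\hat\sigma_{11}}{2t}\,\lVert y_2^{(2)} - X_2\beta^{(2)}\rVert_2^2
 + \tfrac12 \log t
 + \lambda_1 \lVert\beta^{(1)}\rVert_1 + \lambda_2 \lVert\beta^{(2)}\rVert_1 $$

subject to $\lVert\beta^{(1)} - \beta^{(2)}\rVert < \xi$, where the
$\hat\sigma$ are plug-in summaries of the implied 2×2 phenotype
covariance $\Sigma$ and $t = |\Sigma|$ (see `covariance_summary()` for
the exact expressions, including the confounder trace terms). Note the
*crossed* weights: cohort 1's residual is weighted by $\hat\sigma_{22}$.
The coupling constraint encodes the prior that the two phenotypes share
genetic architecture; its radius $\xi$ never needs to be chosen because
the constraint is realized through the ADMM splitting itself.

### Solver

`solve_cmm()` alternates two steps (after the variance components have
been estimated once and frozen — the P3D convention, "population
parameters previously determined"):

1. recompute $\hat\sigma_{11}, \hat\sigma_{22}, \hat\sigma_{12}, t$ at
   the current coefficients;
2. with those weights fixed, minimize the resulting doubly-penalized
   least-squares problem by **consensus ADMM**: blocks $\beta^{(1)}$ and
   $\beta^{(2)}$ are tied to a consensus variable $z$ with augmented-
   Lagrangian penalty `rho`; each block update is an
   $\ell_2$-regularized lasso solved by coordinate descent with
   soft-thresholding; the $z$-update averages.

The solver returns the *block iterates*, not the consensus: at finite
tolerance the two coefficient vectors differ, which is exactly what
makes per-phenotype rankings (and their intersection) meaningful.

Design choices worth knowing about, made where the published record is
silent:

* **Objective trace and monotone safeguard.** The reported
  `objective_trace` evaluates the full objective with the covariance
  summaries recomputed at the current iterate. A full ADMM step can
  overshoot this objective (the refreshed $\log t$ term penalizes dense,
  large-magnitude fits); the solver then backtracks along the segment
  toward the previous iterate, halving the step up to twelve times, and
  stops at the previous iterate if no descent step exists. The trace is
  therefore non-increasing by construction — a property the test suite
  checks on random instances rather than assumes.
* **Inexact inner solves.** Inside the ADMM loop each block update runs
  at most `cd_inner_sweeps = 50` coordinate-descent sweeps (warm
  started). Cheaper updates (5 sweeps) made the consensus loop diverge
  in profiling; 50 is stable in all regimes we exercised and roughly an
  order of magnitude faster than solving each block to full tolerance.
* **Determinant floor.** `t` is clamped at `t_min_frac * s11 * s22`
  (default 1e-8) so `log t` stays defined near-singular $\Sigma$;
  clamping events are recorded in the estimate's notes.
* **Weight refresh schedule.** $t$ and the $\hat\sigma$ are updated
  between outer iterations, not inside the ADMM loop, and are treated
  as constants within each block subproblem.
* **Initialization** is deterministic: $\beta = 0$, duals $= 0$, weights
  from the zero-coefficient summary.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda1`, `lambda2` | tuned | l1 penalties (per phenotype) |
| `rho` | 1.0 | coupling strength of the consensus split |
| `outer_tol` | 1e-5 | relative objective change to stop the outer loop |
| `max_outer` | 50 | outer iteration cap |
| `admm_tol` | 1e-5 | primal/dual residual tolerance |
| `max_admm` | 1000 | ADMM iteration cap per outer pass |
| `t_min_frac` | 1e-8 | determinant floor fraction |

Larger `rho` pulls the two coefficient vectors together (the test suite
verifies the consensus gap is non-increasing in `rho`); `rho = 0`
decouples the studies entirely and reduces each block to an ordinary
lasso, which is how the solver is validated against independent lasso
oracles.

## Variance components (P3D)

`estimate_components()` fits the null model
`y ~ N(0, sigma_u^2 K + sigma_v^2 I)` per cohort by maximum likelihood:
one eigendecomposition of `K`, then a profile likelihood in the ratio
`delta = sigma_v^2 / sigma_u^2` over a 100-point log grid on
`[1e-5, 1e5]` refined by bounded scalar minimization (tolerance 1e-8).
The kinship is `X X' / p` on column-standardized genotypes; the `1/p`
factor keeps `tr(K) = n` and only rescales `sigma_u^2`, which the
covariance summaries use consistently. When `K` is numerically a
multiple of the identity the two components are not separately
identifiable; the function then returns `(0, var(y))` with a warning
rather than an arbitrary split. A phenotype intercept is profiled out by
centering; REML and more sophisticated kinship constructions are
deliberately out of scope.

## Hyperparameter selection

Three modes, mirroring the tool's command line:

* `--snum k`: **binary search** on a shared log-scale multiplier of
  both penalties over `[1e-5, 1e5]`, stopping as soon as each cohort
  reports a nonzero-coefficient count within **50–200%** of `k`. Lasso
  support is not exactly monotone in the penalty (warm starts make it
  only approximately so), so the search tracks the best candidate seen
  and falls back to per-cohort refinement when a shared multiplier
  cannot satisfy both cohorts.
* `--lambda v`: fixed penalty, no search.
* neither: **five-fold cross-validation** on a penalty grid, folds
  seeded and stratified on binary phenotypes, scored by held-out squared
  error of the linear predictor summed over both cohorts. Squared error
  is used even for case/control data, consistent with the linear
  treatment of binary traits throughout.

Selected SNPs are ranked by `|beta|` descending per phenotype (ties
broken by panel order) and the jointly-selected set is the intersection
of the two id lists.

## What the synthetic generator emulates — and what it does not

`simulate_paired_study()` is the package's stand-in for a forward
population simulation. Its stated world:

* **Population structure** by the Balding–Nichols model: ancestral
  frequency `f ~ U(maf_range)`, subpopulation frequencies
  `Beta(f(1-fst)/fst, (1-f)(1-fst)/fst)`, dosages `Binomial(2, freq)`.
  Defaults: 3 subpopulations, `fst = 0.1`, `maf_range = [0.05, 0.5]`.
  The two cohorts share subpopulation frequencies but mix the
  subpopulations differently (cohort 1 equally; cohort 2 with a linear
  1:1.5:2 skew), emulating independent collection from one structured
  population.
* **Confounders**: `u ~ N(0, sigma_u_sq K_i)` drawn fresh per
  (cohort, phenotype) with `sigma_u_sq = 1`, and one collection effect
  `v ~ N(0, sigma_v_sq I)` per cohort (`sigma_v_sq = 1`) shared by both
  phenotypes of that cohort, exactly as the generative model dictates.
* **Sparse effects**: `frac_causal` of SNPs per phenotype (swept over
  0.1%–1% in the simulation study), a `frac_common` fraction of them
  shared with *identical* effect values across phenotypes.
* **SNR calibration**: effects are drawn `N(0,1)` and rescaled by one
  shared multiplier so that the mean over the two observed phenotypes of
  `Var(X beta) / Var(u + v)` equals `target_snr = 0.25`. A per-phenotype
  multiplier would hit 0.25 exactly for each phenotype but would break
  the identical-common-effects invariant; with the shared multiplier the
  two per-phenotype ratios scatter around 0.25 (typically ±0.05 at the
  default sizes) while their mean is exact. The definition of SNR
  (aggregate variance ratio on the liability scale, not per-SNP) is a
  documented choice.
* **Binary phenotypes** by thresholding the liability at its median,
  giving balanced cases/controls.

Not emulated: linkage disequilibrium and recombination block structure,
forward-time demography, dominance and epistasis, genotyping error. A
green simulation test therefore establishes correct behaviour under
idealized independent-SNP stratified genotypes, not under real LD
patterns.

## Evaluation harness

The in-scope baselines are per-study Wald tests (`wald_univariate`),
LMM-whitened tests (`lmm_univariate`, using the P3D components),
BH FDR selection and the hypergeometric overlap test, the merged-cohort
pseudo-phenotype test (`cd_merge_test`), and the joint (consensus)
lasso (`joint_lasso`) — the coupled solver with unit weights and no
covariance re-weighting, i.e. coupling without confounder correction.
ROC curves for recovering the *common* SNPs call a SNP only when it is
selected for both phenotypes: p-value methods sweep a shared threshold
(equivalently, threshold the per-SNP worst-of-two p-value); path methods
contribute one point per penalty on a log grid spanning `[1e-5, 1e5]`
(200 points at full scale, fewer at desk scale — grid points above the
analytic shrinkage threshold are counted as empty without solving, and
the path stops once essentially everything is selected, since both ends
only duplicate the ROC endpoints). AUC is the trapezoid over the
achieved points; for full-sweep score methods this equals the
Mann–Whitney statistic, which the tests verify.

In the bundled desk-scale comparison (n = 500, p = 5000, 0.1% causal
SNPs, half of them shared), the coupled model's mean AUC exceeds both
the joint lasso's and the merged-data baseline's — the qualitative
ordering the method is designed for; the acceptance suite recomputes
exactly this.

## Numerical and degenerate-input conventions

* Genotype standardization uses the population (denominator `n`)
  variance; monomorphic SNPs standardize to all-zero and are flagged,
  never dropped silently.
* Missing genotypes are imputed to the per-SNP mean dosage before
  standardization; SNPs missing everywhere are dropped with a warning.
* Allele harmonization between cohorts: same allele pair kept, swapped
  pair flipped (`d -> 2 - d`), anything else dropped with a warning.
  Strand-ambiguous (A/T, C/G) SNPs are only swap-flipped — real data
  would need strand checks that a simulation-backed package cannot
  exercise.
* SNP ordering after intersection is deterministic: chromosome,
  position, id.
* Ties in effect-size ranking preserve panel order, making reports
  byte-reproducible under a fixed seed.

## Known limitations

* The exact update schedule of the original solver is unpublished; the
  alternating scheme with monotone safeguard is this package's
  reconstruction, and at very small penalties it may legitimately stop
  early (dense overfit solutions can be worse than sparse ones under
  the full likelihood, because of the $\log t$ term).
* Coefficients come with no standard errors or p-values — the method is
  selection-based by design.
* Binary traits are modelled linearly throughout (as in the original
  method); no logistic likelihood.
* The latent cross-phenotypes are replaced by point predictions, not
  marginalized.
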