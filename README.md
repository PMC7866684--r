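# coupledmm

Joint GWAS analysis of **two independently collected cohorts with two
different phenotypes**, on individual-level PLINK data, with explicit
correction of the confounding that wrecks naive joint analyses.

## Who this is for

You have cohort 1 genotyped and phenotyped for disease A, and cohort 2 —
collected by someone else, elsewhere — genotyped and phenotyped for
disease B. You want the SNPs associated with *both* diseases. Neither
cohort measured the other's phenotype, the cohorts have different
population structure, and each carries its own collection (batch)
artifacts. Summary-statistic meta-analysis discards the genotype-level
information that lets you model those confounders; this package uses it.

## The model

For cohort $i \in \{1,2\}$ and phenotype $j \in \{1,2\}$:

$$ y_i^{(j)} = X_i\,\beta^{(j)} + u_i^{(j)} + v_i + \epsilon_i^{(j)},
\qquad
u_i^{(j)} \sim N(0,\, \sigma_{u^{(j)}}^2 K_i), \quad
v_i \sim N(0,\, \sigma_{v_i}^2 I), $$

where $K_i = X_i X_i'/p$ is the kinship matrix, $u$ captures
population-structure confounding (phenotype-specific variance), $v$
captures collection/batch confounding (cohort-specific variance), and
only $y_1^{(1)}$, $y_2^{(2)}$ are observed. The unidentifiable residual
$\epsilon$ is dropped at estimation time. Replacing the unobserved
cross-phenotypes by their predictions ($y_1^{(2)} \to X_1\beta^{(2)}$,
$y_2^{(1)} \to X_2\beta^{(1)}$) gives the coupled sparse objective

$$ \min_{\beta^{(1)},\beta^{(2)},t}\;
\frac{\hat\sigma_{22}}{2t}\lVert y_1^{(1)}-X_1\beta^{(1)}\rVert_2^2 +
\frac{\hat\sigma_{11}}{2t}\lVert y_2^{(2)}-X_2\beta^{(2)}\rVert_2^2 +
\tfrac12\log t + \lambda_1\lVert\beta^{(1)}\rVert_1 +
\lambda_2\lVert\beta^{(2)}\rVert_1 $$

subject to $\lVert\beta^{(1)}-\beta^{(2)}\rVert < \xi$, with
$t = |\hat\Sigma|$ the determinant of the implied 2×2 phenotype
covariance. Variance components are estimated once per cohort under the
null (P3D) and held fixed; $\{\beta^{(1)}, \beta^{(2)}\}$ and $t$ are
then estimated by an alternating scheme whose inner problem is solved
by consensus ADMM (the coupling constraint is absorbed by the ADMM
splitting, so $\xi$ is never tuned). Coordinate descent with
soft-thresholding handles each $\ell_1$ block; the compiled core lives
in `src/`. See the vignette
(`vignettes/coupled-mixed-model.Rmd`) for the solver's design decisions.

## Worked example

Simulate a paired study (two cohorts of 300, 1000 SNPs, 5 causal SNPs
per phenotype of which 3 shared, stratified genotypes, both confounder
classes, aggregate signal-to-noise 0.25), write it through the real
PLINK path, and run the full pipeline asking for ~5 SNPs per cohort:

```r
library(coupledmm)

sc  <- simulation_config(n = 300, p = 1000, frac_causal = 0.005,
                         frac_common = 0.6, target_snr = 0.25, seed = 42)
sim <- simulate_paired_study(sc)
dir <- file.path(tempdir(), "cmm-demo")
paths <- write_paired_study(sim, dir, "study")

fast <- solver_config(max_admm = 150, admm_tol = 1e-4, max_outer = 20)
res  <- cmm_run(paths[["prefix1"]], paths[["prefix2"]],
                out_dir = file.path(dir, "out"),
                snum = 5, seed = 1, config = fast)
print(res)
res$common
```

Output actually printed by this code:

```
SelectionResult: 10 + 2 SNPs selected, 2 common
  queried k = 5, achieved = (10, 2), success = FALSE
[1] "snp000052" "snp000129"
```

Reading this: the binary search on the shared penalty multiplier looked
for a penalty where *both* cohorts report within 50–200% of the queried
5 SNPs; on this deliberately confounded instance cohort 2's support
jumps from 2 straight past the window, so the search reports its
closest solution with `success = FALSE` rather than pretending. The two
jointly selected SNPs, `snp000052` and `snp000129`, are two of the
three truly shared causal SNPs (`sim$truth$common` = 52, 129, 636), and
they top both cohorts' |effect| rankings. The run directory contains
`cmm_results.tsv` (per-SNP effects, ranks, selection and common flags)
and `cmm_manifest.json` (variance components — here
$\hat\sigma^2_{u}\approx 0.07$–$0.08$, $\hat\sigma^2_{v}\approx
0.14$–$0.18$ on the 0/1 phenotype scale — chosen penalty, convergence
trace, warnings).

Command-line equivalents (installed under `inst/cli/`):

```sh
cmm run --file1 study1 --file2 study2 --snum 30 --out results --seed 1
cmm simulate --config sim.json --out simout
```

`cmm run` modes mirror the three tuning strategies: `--snum k` (binary
search with the 50–200% rule), `--lambda v` (fixed penalty), neither
(five-fold cross-validation).

## The simulation study

`cmm_simulate()` sweeps `frac_causal` × `frac_common` × seeds, runs the
baseline panel — per-cohort Wald and LMM tests with BH selection and
hypergeometric overlap, the merged-cohort pseudo-phenotype test, the
joint (consensus) lasso, optionally l1 logistic regression — and writes
per-cell AUC tables and ROC point files for recovering the SNPs
associated with both phenotypes. At the bundled desk scale (n = 500,
p = 5000, 0.1% causal, half shared, 5 seeds) the mean AUCs computed by
the acceptance suite are CMM 0.98, merged-data 0.94, joint lasso 0.86 —
the qualitative ordering the coupled model is built for.

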