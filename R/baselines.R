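## Baseline panel: univariate Wald tests, LMM-whitened tests, the
## merged-data pseudo-phenotype test, BH FDR control, the
## hypergeometric overlap test, and the joint (consensus) lasso.

#' Univariate Wald association tests
#'
#' Simple linear regression of the centered phenotype on each SNP
#' column separately; two-sided p-value of the Wald statistic
#' `beta / se(beta)` against the t distribution with `n - 2` degrees of
#' freedom (the intercept is absorbed by centering but still counted).
#' Monomorphic SNPs get `p = 1`.
#'
#' @param X standardized (or at least centered) `n x p` dosage matrix.
#' @param y phenotype vector; centered internally.
#' @return list with `p_values`, `beta`, `t_stat` (length-p vectors).
#' @export
wald_univariate <- function(X, y) {
  if (inherits(X, "GenotypeStudy")) { y <- X$y; X <- X$X }
  n <- nrow(X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X), "-")
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  mono <- sxx <= 1e-12
  beta <- ifelse(mono, 0, sxy / ifelse(mono, 1, sxx))
  rss <- pmax(sum(yc^2) - beta^2 * sxx, 0)
  df <- n - 2
  se <- sqrt(rss / df / ifelse(mono, 1, sxx))
  tstat <- ifelse(mono | se <= 0, 0, beta / se)
  pv <- 2 * stats::pt(-abs(tstat), df = df)
  pv[mono] <- 1
  # a perfect fit (nonzero slope, zero residual) gives se = 0; report
  # the smallest representable p rather than NaN.  A constant phenotype
  # also gives se = 0 but with slope 0: that stays at p = 1.
  pv[!mono & se <= 0 & beta != 0] <- .Machine$double.xmin
  list(p_values = pv, beta = beta, t_stat = tstat)
}

#' LMM-whitened univariate association tests
#'
#' Generalized least squares against the null covariance
#' `V = sigma_u^2 K + sigma_v^2 I`: `V^{-1/2}` is formed once by
#' eigendecomposition and both phenotype and genotypes are whitened,
#' then each SNP is Wald-tested on the transformed data.  With
#' `sigma_u_sq = 0` this reduces exactly to [wald_univariate()].
#'
#' @param X `n x p` dosage matrix (standardized).
#' @param y phenotype vector.
#' @param K kinship matrix (a [compute_kinship()] result or plain matrix).
#' @param sigma_u_sq,sigma_v_sq variance components from
#'   [estimate_components()] (P3D).
#' @return list with `p_values`, `beta`, `t_stat`.
#' @export
lmm_univariate <- function(X, y, K, sigma_u_sq, sigma_v_sq) {
  if (inherits(K, "KinshipMatrix")) K <- K$K
  n <- nrow(X)
  yc <- y - mean(y)
  V_floor <- 1e-10
  eg <- eigen(sigma_u_sq * K, symmetric = TRUE)
  dV <- pmax(eg$values, 0) + sigma_v_sq
  if (all(dV <= V_floor)) stop("null covariance V is not positive definite")
  dV <- pmax(dV, V_floor)
  Wt <- sweep(t(eg$vectors), 1, sqrt(dV), "/")   # V^{-1/2} rotation
  wald_univariate(Wt %*% X, drop(Wt %*% yc))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard FDR control: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' find the largest `k` with `p_(k) <= q k / m` and reject the `k`
#' smallest.
#'
#' @param pvals numeric vector of p-values.
#' @param q target false discovery rate in (0, 1).
#' @return integer vector of rejected indices (possibly empty).
#' @export
bh_procedure <- function(pvals, q) {
  stopifnot(q > 0, q < 1, all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  ord <- order(pvals)
  ok <- which(pvals[ord] <= q * seq_len(m) / m)
  if (length(ok) == 0) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `m` overlapping SNPs
#' when `k1` and `k2` SNPs are drawn independently without replacement
#' from a panel of `p_total`.
#'
#' @param p_total panel size.
#' @param k1,k2 per-study selected counts.
#' @param m observed overlap, `m <= min(k1, k2)`.
#' @return scalar p-value.
#' @export
hypergeometric_overlap <- function(p_total, k1, k2, m) {
  if (any(c(p_total, k1, k2, m) < 0) || k1 > p_total || k2 > p_total ||
      m > min(k1, k2))
    stop("invalid counts: need m <= min(k1, k2) <= p_total")
  if (m == 0) return(1)
  stats::phyper(m - 1, k1, p_total - k1, k2, lower.tail = FALSE)
}

#' Merged-data pseudo-phenotype test (CD baseline)
#'
#' Stacks the two cohorts, `X = [X1; X2]`, and forms a pseudo phenotype
#' that is 1 iff a sample is a case in its own study, then runs
#' [wald_univariate()] on the merged data.
#'
#' @param study1,study2 [genotype_study()] objects on the same panel
#'   with binary phenotypes.
#' @return list with `p_values`, `beta`, `t_stat`, `n_merged`.
#' @export
cd_merge_test <- function(study1, study2) {
  if (!identical(study1$variants$id, study2$variants$id))
    stop("studies must share the SNP panel (run intersect_snps first)")
  X <- rbind(study1$X, study2$X)
  y <- c(as.numeric(study1$y != 0), as.numeric(study2$y != 0))
  out <- wald_univariate(X, y)
  out$n_merged <- nrow(X)
  out
}

#' Joint lasso (JL baseline)
#'
#' The coupled solver without confounder correction: unit residual
#' weights, no covariance re-weighting, and ADMM driven to consensus so
#' that a single coefficient vector (`beta1 = beta2 = z`) is returned
#' for both phenotypes.  Equivalent to a lasso on the stacked data with
#' penalty `lambda1 + lambda2` when the designs coincide.
#'
#' @param paired a [paired_study()] (standardized genotypes; phenotypes
#'   centered internally).
#' @param lambda penalty applied to each block (`lambda1 = lambda2 =
#'   lambda`).
#' @param rho ADMM penalty (default 1).
#' @param config a [solver_config()]; consensus is enforced with
#'   `admm_tol` capped at 1e-6.
#' @param warm optional warm start.
#' @return list with `beta1`, `beta2` (both equal to the consensus),
#'   `z`, `n_iter`, `converged`, `state`.
#' @export
joint_lasso <- function(paired, lambda, rho = 1.0, config = solver_config(),
                        warm = NULL) {
  config$lambda1 <- lambda
  config$lambda2 <- lambda
  config$rho <- rho
  config$admm_tol <- min(config$admm_tol, 1e-6)
  paired$study1$y <- paired$study1$y - mean(paired$study1$y)
  paired$study2$y <- paired$study2$y - mean(paired$study2$y)
  fit <- solve_betas_admm(paired, weights = c(1, 1), config, warm = warm)
  z <- fit$z
  # at the consensus fixed point z equals the (sparse) blocks; clean the
  # numerically-tiny entries where both blocks agree on exact zero
  z[fit$beta1 == 0 & fit$beta2 == 0] <- 0
  list(beta1 = z, beta2 = z, z = z, n_iter = fit$n_iter,
       converged = fit$converged,
       state = fit[c("beta1", "beta2", "z", "u1", "u2")])
}
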