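## The coupled mixed-model estimator: covariance summaries, the coupled
## objective, the consensus-ADMM block solver, and the outer alternating
## loop that decouples {beta1, beta2} from the determinant t.

#' Solver configuration
#'
#' @param lambda1,lambda2 nonnegative l1 penalty weights for the two
#'   coefficient vectors.
#' @param rho ADMM augmented-Lagrangian penalty coupling the two blocks
#'   (the "similar effect vectors" constraint); `rho = 0` decouples them.
#' @param admm_tol primal/dual residual tolerance of the consensus ADMM.
#' @param outer_tol relative objective-change tolerance of the outer
#'   alternating loop.
#' @param max_outer,max_admm iteration caps.
#' @param t_min_frac determinant floor as a fraction of `s11 * s22`.
#' @param cd_tol,cd_max_sweeps coordinate-descent tolerances within each
#'   block update.
#' @param cd_inner_sweeps CD sweeps per block update *inside* the ADMM
#'   loop (inexact block minimization; the duals absorb the residual
#'   error).
#' @param seed integer seed recorded in the config (the solver itself is
#'   deterministic).
#' @return An object of class `SolverConfig`.
#' @export
solver_config <- function(lambda1 = 1, lambda2 = 1, rho = 1.0,
                          admm_tol = 1e-5, outer_tol = 1e-5,
                          max_outer = 50L, max_admm = 1000L,
                          t_min_frac = 1e-8,
                          cd_tol = 1e-7, cd_max_sweeps = 500L,
                          cd_inner_sweeps = 50L,
                          seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, rho >= 0,
            admm_tol > 0, outer_tol > 0, t_min_frac > 0, cd_tol > 0,
            max_outer >= 1, max_admm >= 1, cd_max_sweeps >= 1,
            cd_inner_sweeps >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, rho = rho,
                 admm_tol = admm_tol, outer_tol = outer_tol,
                 max_outer = as.integer(max_outer),
                 max_admm = as.integer(max_admm),
                 t_min_frac = t_min_frac,
                 cd_tol = cd_tol, cd_max_sweeps = as.integer(cd_max_sweeps),
                 cd_inner_sweeps = as.integer(cd_inner_sweeps),
                 seed = as.integer(seed)),
            class = "SolverConfig")
}

.ktrace <- function(K) {
  if (inherits(K, "KinshipMatrix")) sum(diag(K$K)) else sum(diag(as.matrix(K)))
}

#' Covariance summaries of the coupled likelihood
#'
#' Plug-in estimates of the 2x2 phenotype covariance `Sigma` obtained by
#' replacing the unobserved cross-study phenotypes with their model
#' predictions (`y1^(2) -> X1 beta2`, `y2^(1) -> X2 beta1`):
#' \deqn{s11 = y1'y1 + beta1' X2'X2 beta1 + 2 tr(K1) \sigma_{u1}^2 +
#'   \sigma_{v1}^2 + \sigma_{v2}^2}
#' symmetrically for `s22`, and
#' \deqn{s12 = y1' X1 beta2 + beta1' X2' y2 + tr(K1)\sigma_{u1}^2 +
#'   tr(K2)\sigma_{u2}^2 + \sigma_{v1}^2 + \sigma_{v2}^2.}
#' The determinant `t = s11 s22 - s12^2` is floored at
#' `t_min = t_min_frac * s11 * s22` so that `log t` stays defined; a
#' clamping event is recorded in the `clamped` field.
#'
#' @param beta1,beta2 coefficient vectors of length `p`.
#' @param paired a [paired_study()] (standardized genotypes, centered
#'   phenotypes).
#' @param vc a [variance_components()] object.
#' @param K1,K2 kinship matrices (or their traces as scalars).
#' @param t_min_frac determinant floor fraction.
#' @return An object of class `CovarianceSummary`: `s11`, `s22`, `s12`,
#'   `t`, `t_raw`, `clamped`.
#' @export
covariance_summary <- function(beta1, beta2, paired, vc, K1, K2,
                               t_min_frac = 1e-8) {
  X1 <- paired$study1$X; X2 <- paired$study2$X
  y1 <- paired$study1$y; y2 <- paired$study2$y
  p <- ncol(X1)
  if (length(beta1) != p || length(beta2) != p)
    stop("beta vectors must have length p = ", p)
  tr1 <- if (is.matrix(K1) || inherits(K1, "KinshipMatrix")) .ktrace(K1) else K1
  tr2 <- if (is.matrix(K2) || inherits(K2, "KinshipMatrix")) .ktrace(K2) else K2

  X2b1 <- drop(X2 %*% beta1)
  X1b2 <- drop(X1 %*% beta2)
  s11 <- sum(y1^2) + sum(X2b1^2) + 2 * tr1 * vc$sigma_u1_sq +
    vc$sigma_v1_sq + vc$sigma_v2_sq
  s22 <- sum(y2^2) + sum(X1b2^2) + 2 * tr2 * vc$sigma_u2_sq +
    vc$sigma_v1_sq + vc$sigma_v2_sq
  s12 <- sum(y1 * X1b2) + sum(X2b1 * y2) +
    tr1 * vc$sigma_u1_sq + tr2 * vc$sigma_u2_sq +
    vc$sigma_v1_sq + vc$sigma_v2_sq
  t_raw <- s11 * s22 - s12^2
  t_min <- t_min_frac * s11 * s22
  clamped <- t_raw < t_min
  structure(list(s11 = s11, s22 = s22, s12 = s12,
                 t = max(t_raw, t_min), t_raw = t_raw, clamped = clamped),
            class = "CovarianceSummary")
}

#' @export
print.CovarianceSummary <- function(x, ...) {
  cat(sprintf("CovarianceSummary: s11 = %.4g, s22 = %.4g, s12 = %.4g, t = %.4g%s\n",
              x$s11, x$s22, x$s12, x$t, if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Coupled objective with fixed covariance weights
#'
#' The negative log-likelihood surrogate minimized by the solver, with
#' the covariance summaries treated as constants:
#' \deqn{(s22/2t)||y1 - X1 b1||^2 + (s11/2t)||y2 - X2 b2||^2 +
#'   (1/2)\log t + \lambda_1 ||b1||_1 + \lambda_2 ||b2||_1.}
#' Note the crossed weights: study 1's residual is weighted by `s22`,
#' study 2's by `s11`.
#'
#' @param beta1,beta2 coefficient vectors.
#' @param t determinant value, must be positive.
#' @param paired a [paired_study()].
#' @param config a [solver_config()] (supplies `lambda1`, `lambda2`).
#' @param summary_fixed a [covariance_summary()] supplying `s11`, `s22`.
#' @return scalar objective value.
#' @export
cmm_objective <- function(beta1, beta2, t, paired, config, summary_fixed) {
  if (t <= 0) stop("t must be positive (clamp upstream)")
  r1 <- paired$study1$y - drop(paired$study1$X %*% beta1)
  r2 <- paired$study2$y - drop(paired$study2$X %*% beta2)
  (summary_fixed$s22 / (2 * t)) * sum(r1^2) +
    (summary_fixed$s11 / (2 * t)) * sum(r2^2) +
    0.5 * log(t) +
    config$lambda1 * sum(abs(beta1)) +
    config$lambda2 * sum(abs(beta2))
}

#' Solve the coupled block problem for fixed weights
#'
#' Consensus ADMM for
#' `w1 ||y1 - X1 b1||^2 + w2 ||y2 - X2 b2||^2 + lambda1 ||b1||_1 +
#' lambda2 ||b2||_1` under the coupling `b1 ~ b2`, realized as an
#' augmented-Lagrangian consensus split (`b1 = z`, `b2 = z`) with scaled
#' duals and penalty `rho`.  Block updates are l2-regularized lasso
#' subproblems solved by coordinate descent with soft-thresholding; the
#' z-update averages.  The *block iterates* are returned (not the
#' consensus), so the two coefficient vectors can differ at termination
#' — this is what makes per-phenotype rankings possible.
#'
#' @param paired a [paired_study()].
#' @param weights length-2 numeric `(w1, w2)`; in the coupled model
#'   `w1 = s22 / 2t` and `w2 = s11 / 2t`.
#' @param config a [solver_config()].
#' @param warm optional list with `beta1`, `beta2`, `z`, `u1`, `u2` to
#'   warm-start from.
#' @return list with `beta1`, `beta2`, `z`, `u1`, `u2`, `n_iter`,
#'   `converged`.
#' @export
solve_betas_admm <- function(paired, weights, config, warm = NULL) {
  X1 <- paired$study1$X; X2 <- paired$study2$X
  y1 <- paired$study1$y; y2 <- paired$study2$y
  p <- ncol(X1)
  zero <- numeric(p)
  b1 <- if (!is.null(warm$beta1)) warm$beta1 else zero
  b2 <- if (!is.null(warm$beta2)) warm$beta2 else zero
  z  <- if (!is.null(warm$z))  warm$z  else zero
  u1 <- if (!is.null(warm$u1)) warm$u1 else zero
  u2 <- if (!is.null(warm$u2)) warm$u2 else zero
  res <- admm_consensus(X1, y1, X2, y2,
                        weights[1], weights[2],
                        config$lambda1, config$lambda2, config$rho,
                        b1, b2, z, u1, u2,
                        config$max_admm, config$admm_tol,
                        config$cd_max_sweeps, config$cd_tol,
                        if (is.null(config$cd_inner_sweeps)) 50L
                        else config$cd_inner_sweeps)
  res$beta1 <- drop(res$beta1); res$beta2 <- drop(res$beta2)
  res$z <- drop(res$z); res$u1 <- drop(res$u1); res$u2 <- drop(res$u2)
  res
}

#' Fit the coupled mixed model
#'
#' Outer alternating loop: (i) recompute the covariance summaries and
#' determinant `t` at the current coefficients; (ii) with those weights
#' fixed, solve the coupled sparse block problem by consensus ADMM.
#' Variance components are estimated beforehand and never re-estimated
#' here (P3D).  The recorded objective trace evaluates the full
#' objective (weights recomputed at the current iterate) and is
#' guaranteed non-increasing: a weight update that would increase the
#' objective reverts to the previous iterate and stops (monotone
#' safeguard).
#'
#' @param paired a [paired_study()] with standardized genotypes; the
#'   phenotypes are centered internally.
#' @param vc a [variance_components()] object.
#' @param lambda1,lambda2 l1 penalties (override the config's).
#' @param config a [solver_config()].
#' @param K1,K2 kinship matrices or traces; default `tr(K) = n` which is
#'   exact for `X X'/p` kinship on fully polymorphic standardized panels.
#' @param warm optional warm start (as in [solve_betas_admm()]).
#' @return An object of class `CoupledEstimate`: `beta1`, `beta2`,
#'   `summary`, `objective_trace`, `converged`, `n_outer`,
#'   `n_admm_total`, `notes`, plus the final ADMM state in `state` for
#'   warm-starting path computations.
#' @export
solve_cmm <- function(paired, vc, lambda1 = NULL, lambda2 = NULL,
                      config = solver_config(), K1 = NULL, K2 = NULL,
                      warm = NULL) {
  if (!is.null(lambda1)) config$lambda1 <- lambda1
  if (!is.null(lambda2)) config$lambda2 <- lambda2
  # center phenotypes (idempotent; intercept is profiled out)
  paired$study1$y <- paired$study1$y - mean(paired$study1$y)
  paired$study2$y <- paired$study2$y - mean(paired$study2$y)
  n1 <- nrow(paired$study1$X); n2 <- nrow(paired$study2$X)
  p <- ncol(paired$study1$X)
  tr1 <- if (is.null(K1)) n1 else .ktrace(K1)
  tr2 <- if (is.null(K2)) n2 else .ktrace(K2)

  beta1 <- if (!is.null(warm$beta1)) warm$beta1 else numeric(p)
  beta2 <- if (!is.null(warm$beta2)) warm$beta2 else numeric(p)
  state <- warm
  notes <- character(0)

  summ <- covariance_summary(beta1, beta2, paired, vc, tr1, tr2,
                             config$t_min_frac)
  obj <- cmm_objective(beta1, beta2, summ$t, paired, config, summ)
  trace <- obj
  n_admm_total <- 0L
  converged <- FALSE

  for (iter in seq_len(config$max_outer)) {
    w <- c(summ$s22 / (2 * summ$t), summ$s11 / (2 * summ$t))
    fit <- solve_betas_admm(paired, w, config, warm = state)
    n_admm_total <- n_admm_total + fit$n_iter
    new_beta1 <- fit$beta1; new_beta2 <- fit$beta2
    new_summ <- covariance_summary(new_beta1, new_beta2, paired, vc,
                                   tr1, tr2, config$t_min_frac)
    if (new_summ$clamped)
      notes <- c(notes, sprintf("outer %d: determinant clamped to t_min", iter))
    new_obj <- cmm_objective(new_beta1, new_beta2, new_summ$t, paired,
                             config, new_summ)
    if (new_obj > obj + 1e-6) {
      # monotone safeguard: the full ADMM step overshoots the coupled
      # objective (the refreshed log-determinant term penalizes it);
      # backtrack along the segment to the previous iterate
      accepted <- FALSE
      for (s in 2^-(1:12)) {
        cand1 <- beta1 + s * (new_beta1 - beta1)
        cand2 <- beta2 + s * (new_beta2 - beta2)
        cand_summ <- covariance_summary(cand1, cand2, paired, vc,
                                        tr1, tr2, config$t_min_frac)
        cand_obj <- cmm_objective(cand1, cand2, cand_summ$t, paired,
                                  config, cand_summ)
        if (cand_obj <= obj + 1e-6 && cand_obj < obj) {
          notes <- c(notes,
                     sprintf("outer %d: backtracked step (s = %g)", iter, s))
          new_beta1 <- cand1; new_beta2 <- cand2
          new_summ <- cand_summ; new_obj <- cand_obj
          fit$beta1 <- cand1; fit$beta2 <- cand2
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        notes <- c(notes,
                   sprintf("outer %d: no descent step found (%.6g > %.6g); stopping",
                           iter, new_obj, obj))
        converged <- TRUE
        break
      }
    }
    beta1 <- new_beta1; beta2 <- new_beta2
    state <- fit[c("beta1", "beta2", "z", "u1", "u2")]
    trace <- c(trace, new_obj)
    rel_change <- abs(obj - new_obj) / max(1, abs(obj))
    obj <- new_obj; summ <- new_summ
    if (rel_change < config$outer_tol) { converged <- TRUE; break }
  }

  structure(list(beta1 = beta1, beta2 = beta2, summary = summ,
                 objective_trace = trace, converged = converged,
                 n_outer = length(trace) - 1L,
                 n_admm_total = n_admm_total,
                 lambda1 = config$lambda1, lambda2 = config$lambda2,
                 notes = notes, state = state),
            class = "CoupledEstimate")
}

#' @export
print.CoupledEstimate <- function(x, ...) {
  cat("CoupledEstimate: p = ", length(x$beta1), " SNPs\n", sep = "")
  cat(sprintf("  nonzero: %d (phenotype 1), %d (phenotype 2)\n",
              sum(x$beta1 != 0), sum(x$beta2 != 0)))
  cat(sprintf("  objective: %.6g after %d outer iterations (%s)\n",
              utils::tail(x$objective_trace, 1), x$n_outer,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Predict the unobserved cross-study phenotype
#'
#' The model's imputation of the phenotype a study never measured:
#' `X %*% beta` with the *other* phenotype's coefficient vector.  For
#' binary use, threshold the returned linear predictor at 0 (phenotypes
#' are centered in the model).
#'
#' @param X dosage matrix (standardized, as used in fitting).
#' @param beta coefficient vector with `length(beta) == ncol(X)`.
#' @return numeric predicted phenotype vector.
#' @export
predict_cross <- function(X, beta) {
  if (inherits(X, "GenotypeStudy")) X <- X$X
  if (ncol(X) != length(beta))
    stop("ncol(X) = ", ncol(X), " != length(beta) = ", length(beta))
  drop(X %*% beta)
}
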