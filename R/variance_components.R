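## Kinship construction and one-time variance-component estimation
## (P3D: population parameters previously determined).

#' Compute a kinship matrix from standardized genotypes
#'
#' `K = X X' / p` following the genetics convention, with a `1/p` factor
#' so that `tr(K)` stays `O(n)` regardless of panel size (the scaling
#' only rescales the associated variance component and is recorded in
#' `scale_note`).
#'
#' @param X standardized `n x p` dosage matrix (or a [genotype_study()]).
#' @return An object of class `KinshipMatrix`: list with `K` (n x n,
#'   symmetric PSD) and `scale_note`.
#' @export
compute_kinship <- function(X) {
  if (inherits(X, "GenotypeStudy")) X <- X$X
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 0L) stop("cannot compute kinship from zero SNPs")
  K <- tcrossprod(X) / p
  K <- (K + t(K)) / 2
  structure(list(K = K, scale_note = "XX^T / p"), class = "KinshipMatrix")
}

#' @export
print.KinshipMatrix <- function(x, ...) {
  cat("KinshipMatrix: ", nrow(x$K), " x ", ncol(x$K),
      " (scaling: ", x$scale_note, ")\n", sep = "")
  invisible(x)
}

#' Estimate null-model variance components for one study
#'
#' Maximum-likelihood fit of the null covariance
#' `y ~ N(0, sigma_u^2 K + sigma_v^2 I)` for one data set, used once and
#' then held fixed during coupled optimization (P3D).  The phenotype is
#' centered (scalar intercept profiled out), `K` is eigendecomposed
#' once, and the likelihood is profiled over the ratio
#' `delta = sigma_v^2 / sigma_u^2` on a 100-point log grid spanning
#' `[1e-5, 1e5]`, refined by bounded scalar minimization.
#'
#' Population-structure variance (`sigma_u^2`, spread along the kinship)
#' and collection/batch variance (`sigma_v^2`, iid) are separately
#' identifiable only when `K` is not a multiple of the identity; for a
#' near-identity `K` the function returns `(0, var(y))` with a warning.
#'
#' @param study a [genotype_study()] (or a numeric phenotype vector).
#' @param K a [compute_kinship()] result (or a plain matrix) on the same
#'   samples.
#' @return list with `sigma_u_sq`, `sigma_v_sq`, `delta`, `loglik`, and
#'   `warnings` (character vector; grid-boundary events are recorded).
#' @export
estimate_components <- function(study, K) {
  y <- if (inherits(study, "GenotypeStudy")) study$y else as.numeric(study)
  Km <- if (inherits(K, "KinshipMatrix")) K$K else as.matrix(K)
  n <- length(y)
  if (nrow(Km) != n) stop("K and y are on different numbers of samples")
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  yc <- y - mean(y)
  warnings_log <- character(0)

  eg <- eigen(Km, symmetric = TRUE)
  d <- pmax(eg$values, 0)

  # near-identity K: sigma_u^2 and sigma_v^2 are not separately
  # identifiable (K ~ c I makes the covariance c*sigma_u^2 + sigma_v^2)
  spread <- (max(d) - min(d)) / max(mean(d), .Machine$double.eps)
  if (spread < 1e-6) {
    warning("kinship is numerically a multiple of the identity; ",
            "sigma_u^2 and sigma_v^2 are not separately identifiable")
    return(list(sigma_u_sq = 0, sigma_v_sq = stats::var(y),
                delta = Inf, loglik = NA_real_,
                warnings = "near-identity kinship"))
  }

  yt <- drop(crossprod(eg$vectors, yc))
  yt2 <- yt^2

  # profile negative log-likelihood over log(delta)
  nll <- function(log_delta) {
    delta <- exp(log_delta)
    dd <- d + delta
    sigma_u <- mean(yt2 / dd)
    if (sigma_u <= 0) return(Inf)
    0.5 * (sum(log(dd)) + n * log(sigma_u) + n * (1 + log(2 * pi)))
  }
  grid <- log(exp(seq(log(1e-5), log(1e5), length.out = 100)))
  vals <- vapply(grid, nll, numeric(1))
  i0 <- which.min(vals)
  if (i0 == 1L || i0 == length(grid)) {
    warnings_log <- c(warnings_log,
                      sprintf("delta optimizer at grid boundary (delta = %g)",
                              exp(grid[i0])))
  }
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(nll, interval = c(lo, hi), tol = 1e-8)
  # keep whichever of (grid best, refined) is better
  if (opt$objective <= vals[i0]) {
    log_delta <- opt$minimum; best_nll <- opt$objective
  } else {
    log_delta <- grid[i0]; best_nll <- vals[i0]
  }
  delta <- exp(log_delta)
  sigma_u <- mean(yt2 / (d + delta))
  list(sigma_u_sq = sigma_u,
       sigma_v_sq = delta * sigma_u,
       delta = delta,
       loglik = -best_nll,
       warnings = warnings_log)
}

#' Export a kinship matrix as TSV
#'
#' Samples-by-samples table with a header row of sample ids, for
#' inspection with external tools.
#'
#' @param K a [compute_kinship()] result (or plain matrix).
#' @param sample_ids character vector of row/column labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(K, sample_ids, path) {
  Km <- if (inherits(K, "KinshipMatrix")) K$K else as.matrix(K)
  stopifnot(length(sample_ids) == nrow(Km))
  df <- as.data.frame(Km)
  names(df) <- sample_ids
  utils::write.table(cbind(id = sample_ids, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle the four confounder variance scalars
#'
#' The coupled model has two phenotype-specific population-structure
#' variances and two data-set-specific collection variances; only
#' `y1^(1)` and `y2^(2)` are observed, so each study contributes one
#' `(sigma_u^2, sigma_v^2)` pair via [estimate_components()].
#'
#' @param sigma_u1_sq,sigma_u2_sq population-confounder variances for
#'   phenotypes 1 and 2.
#' @param sigma_v1_sq,sigma_v2_sq collection-confounder variances for
#'   data sets 1 and 2.
#' @return An object of class `VarianceComponents`.
#' @export
variance_components <- function(sigma_u1_sq, sigma_u2_sq,
                                sigma_v1_sq, sigma_v2_sq) {
  vals <- c(sigma_u1_sq, sigma_u2_sq, sigma_v1_sq, sigma_v2_sq)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("variance components must be finite and nonnegative")
  structure(list(sigma_u1_sq = sigma_u1_sq, sigma_u2_sq = sigma_u2_sq,
                 sigma_v1_sq = sigma_v1_sq, sigma_v2_sq = sigma_v2_sq),
            class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("VarianceComponents:\n")
  cat(sprintf("  sigma_u1^2 = %.4g  sigma_u2^2 = %.4g\n",
              x$sigma_u1_sq, x$sigma_u2_sq))
  cat(sprintf("  sigma_v1^2 = %.4g  sigma_v2^2 = %.4g\n",
              x$sigma_v1_sq, x$sigma_v2_sq))
  invisible(x)
}

#' Estimate all four variance components for a paired study
#'
#' Convenience wrapper running [estimate_components()] on each study
#' (study 1 yields the phenotype-1 and data-set-1 scalars, study 2 the
#' phenotype-2 and data-set-2 scalars).
#'
#' @param paired a [paired_study()] with standardized genotypes.
#' @param K1,K2 optional precomputed kinship matrices.
#' @return A [variance_components()] object with attribute `details`.
#' @export
estimate_paired_components <- function(paired, K1 = NULL, K2 = NULL) {
  if (is.null(K1)) K1 <- compute_kinship(paired$study1)
  if (is.null(K2)) K2 <- compute_kinship(paired$study2)
  e1 <- estimate_components(paired$study1, K1)
  e2 <- estimate_components(paired$study2, K2)
  vc <- variance_components(e1$sigma_u_sq, e2$sigma_u_sq,
                            e1$sigma_v_sq, e2$sigma_v_sq)
  attr(vc, "details") <- list(study1 = e1, study2 = e2)
  vc
}
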