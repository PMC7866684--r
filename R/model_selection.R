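## Hyperparameter selection: binary search on the queried number of
## SNPs with the 50--200% termination rule, a five-fold CV fallback, and
## ranked reporting of selected SNPs.

.count_in_range <- function(counts, k) {
  all(counts >= ceiling(0.5 * k) & counts <= 2 * k)
}

#' Choose penalties by binary search on the queried SNP count
#'
#' Bisects a shared log-scale multiplier applied to both penalties over
#' `[1e-5, 1e5]`, counting nonzero coefficients per data set from
#' [solve_cmm()] with warm starts, and terminates as soon as both data
#' sets report a count within 50--200% of `k_query`.  Because lasso
#' support size is not strictly monotone in the penalty, the best
#' (closest) candidate seen is tracked and returned if the search fails;
#' if exactly one data set's count is out of range after the shared
#' search, that data set's penalty is refined independently.
#'
#' @param paired a [paired_study()] (standardized genotypes).
#' @param vc a [variance_components()] object.
#' @param k_query queried number of SNPs per data set (`>= 1`).
#' @param config a [solver_config()].
#' @param max_search bisection step cap (default 30).
#' @return An object of class `SelectionResult` (see
#'   [rank_and_report()]) with fields `lambda1_star`, `lambda2_star`,
#'   `queried_k`, `achieved_counts`, `success`, and `estimate`.
#' @export
binary_search_lambda <- function(paired, vc, k_query, config = solver_config(),
                                 max_search = 30L) {
  p <- ncol(paired$study1$X)
  if (k_query < 1) stop("k_query must be >= 1")
  if (k_query > p) stop("k_query (", k_query, ") exceeds the SNP count (", p, ")")

  counts_at <- function(lambda1, lambda2, warm = NULL) {
    est <- solve_cmm(paired, vc, lambda1 = lambda1, lambda2 = lambda2,
                     config = config, warm = warm)
    list(est = est, counts = c(sum(est$beta1 != 0), sum(est$beta2 != 0)))
  }
  dist_to_range <- function(counts) {
    # log-scale distance to the acceptance window, so an empty selection
    # is "farther" from k than a moderately dense one
    lo <- ceiling(0.5 * k_query); hi <- 2 * k_query
    d <- log(pmax(lo, 0.5) / (counts + 0.5))
    d[counts >= lo] <- 0
    d2 <- log((counts + 0.5) / hi)
    d2[counts <= hi] <- 0
    sum(abs(d) + abs(d2))
  }

  lo <- 1e-5; hi <- 1e5          # lo: too dense, hi: too sparse
  best <- NULL; warm <- NULL
  success <- FALSE
  for (step in seq_len(max_search)) {
    lam <- sqrt(lo * hi)
    res <- counts_at(lam, lam, warm)
    warm <- res$est$state
    cand <- list(lambda1 = lam, lambda2 = lam,
                 counts = res$counts, est = res$est)
    if (is.null(best) || dist_to_range(res$counts) < dist_to_range(best$counts))
      best <- cand
    if (.count_in_range(res$counts, k_query)) { success <- TRUE; break }
    if (min(res$counts) < ceiling(0.5 * k_query) &&
        max(res$counts) > 2 * k_query) {
      # shared multiplier cannot satisfy both: refine per data set
      break
    }
    if (max(res$counts) > 2 * k_query) lo <- lam else hi <- lam
  }

  if (!success) {
    # independent refinement of whichever penalty is out of range
    lam1 <- best$lambda1; lam2 <- best$lambda2
    for (ds in 1:2) {
      if (best$counts[ds] >= ceiling(0.5 * k_query) &&
          best$counts[ds] <= 2 * k_query) next
      dlo <- 1e-5; dhi <- 1e5
      for (step in seq_len(max_search)) {
        lam <- sqrt(dlo * dhi)
        l1 <- if (ds == 1) lam else lam1
        l2 <- if (ds == 2) lam else lam2
        res <- counts_at(l1, l2, warm)
        warm <- res$est$state
        cand <- list(lambda1 = l1, lambda2 = l2,
                     counts = res$counts, est = res$est)
        if (dist_to_range(res$counts) < dist_to_range(best$counts))
          best <- cand
        if (.count_in_range(res$counts, k_query)) break
        if (res$counts[ds] > 2 * k_query) dlo <- lam else dhi <- lam
      }
      lam1 <- best$lambda1; lam2 <- best$lambda2
    }
    success <- .count_in_range(best$counts, k_query)
  }

  out <- rank_and_report(best$est, k = k_query,
                         snp_ids = paired$common_snp_ids)
  out$lambda1_star <- best$lambda1
  out$lambda2_star <- best$lambda2
  out$queried_k <- as.integer(k_query)
  out$achieved_counts <- as.integer(best$counts)
  out$success <- success
  out
}

.stratified_folds <- function(y, nfolds, seed) {
  n <- length(y)
  folds <- integer(n)
  rng <- .with_seed(seed, {
    if (all(y %in% c(0, 1))) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(nfolds), n))
    }
    folds
  })
  rng
}

#' Five-fold cross-validation over a penalty grid
#'
#' Fallback tuning mode when neither a queried SNP count nor an explicit
#' penalty is given.  Each data set is split into five folds (seeded,
#' stratified on binary phenotypes); for every grid value the coupled
#' model is fit on the training folds of both data sets and scored by
#' held-out squared prediction error on the linear predictor, summed
#' over both data sets.
#'
#' @param paired a [paired_study()].
#' @param vc a [variance_components()] object.
#' @param lambda_grid numeric vector of candidate penalties (applied to
#'   both `lambda1` and `lambda2`).
#' @param config a [solver_config()]; its `seed` fixes the folds.
#' @return list with `lambda1_star`, `lambda2_star`, `cv_error` (per
#'   grid value), `lambda_grid`, `folds1`, `folds2`.
#' @export
five_fold_cv <- function(paired, vc, lambda_grid, config = solver_config()) {
  if (length(lambda_grid) == 0) stop("lambda_grid is empty")
  n1 <- nrow(paired$study1$X); n2 <- nrow(paired$study2$X)
  if (n1 < 10 || n2 < 10) stop("five-fold CV needs at least 10 samples per study")
  nfolds <- 5L
  y1 <- paired$study1$y - mean(paired$study1$y)
  y2 <- paired$study2$y - mean(paired$study2$y)
  f1 <- .stratified_folds(paired$study1$y, nfolds, config$seed)
  f2 <- .stratified_folds(paired$study2$y, nfolds, config$seed + 1L)

  lambda_grid <- sort(lambda_grid, decreasing = TRUE)  # warm-start path
  err <- numeric(length(lambda_grid))
  for (fold in seq_len(nfolds)) {
    tr <- paired
    tr$study1$X <- paired$study1$X[f1 != fold, , drop = FALSE]
    tr$study1$y <- y1[f1 != fold]
    tr$study1$sample_ids <- paired$study1$sample_ids[f1 != fold]
    tr$study2$X <- paired$study2$X[f2 != fold, , drop = FALSE]
    tr$study2$y <- y2[f2 != fold]
    tr$study2$sample_ids <- paired$study2$sample_ids[f2 != fold]
    warm <- NULL
    for (g in seq_along(lambda_grid)) {
      est <- solve_cmm(tr, vc, lambda1 = lambda_grid[g],
                       lambda2 = lambda_grid[g], config = config, warm = warm)
      warm <- est$state
      pred1 <- predict_cross(paired$study1$X[f1 == fold, , drop = FALSE],
                             est$beta1)
      pred2 <- predict_cross(paired$study2$X[f2 == fold, , drop = FALSE],
                             est$beta2)
      err[g] <- err[g] + sum((y1[f1 == fold] - pred1)^2) +
        sum((y2[f2 == fold] - pred2)^2)
    }
  }
  gstar <- which.min(err)
  list(lambda1_star = lambda_grid[gstar], lambda2_star = lambda_grid[gstar],
       cv_error = err, lambda_grid = lambda_grid,
       folds1 = f1, folds2 = f2)
}

#' Rank selected SNPs by effect magnitude
#'
#' Nonzero coefficients are sorted by `|beta|` descending per data set
#' (ties broken by SNP panel order); the jointly selected set is the
#' intersection of the two id lists.
#'
#' @param estimate a [solve_cmm()] result.
#' @param k optional queried count recorded in the result.
#' @param snp_ids optional id vector; defaults to `snp1, snp2, ...`.
#' @return An object of class `SelectionResult`: `selected1`,
#'   `selected2` (ordered id vectors), `common`, and the coefficient
#'   tables `table1`, `table2`.
#' @export
rank_and_report <- function(estimate, k = NULL, snp_ids = NULL) {
  p <- length(estimate$beta1)
  if (is.null(snp_ids)) {
    snp_ids <- attr(estimate, "snp_ids")
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  }
  rank_one <- function(beta) {
    nz <- which(beta != 0)
    if (length(nz) == 0)
      return(data.frame(id = character(0), index = integer(0),
                        beta = numeric(0)))
    ord <- nz[order(-abs(beta[nz]), nz, method = "radix")]
    data.frame(id = snp_ids[ord], index = ord, beta = beta[ord],
               stringsAsFactors = FALSE)
  }
  t1 <- rank_one(estimate$beta1)
  t2 <- rank_one(estimate$beta2)
  structure(list(selected1 = t1$id, selected2 = t2$id,
                 common = intersect(t1$id, t2$id),
                 table1 = t1, table2 = t2,
                 lambda1_star = estimate$lambda1,
                 lambda2_star = estimate$lambda2,
                 queried_k = if (is.null(k)) NA_integer_ else as.integer(k),
                 achieved_counts = c(nrow(t1), nrow(t2)),
                 success = NA,
                 estimate = estimate),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult: ", length(x$selected1), " + ", length(x$selected2),
      " SNPs selected, ", length(x$common), " common\n", sep = "")
  if (!is.na(x$queried_k))
    cat("  queried k = ", x$queried_k, ", achieved = (",
        paste(x$achieved_counts, collapse = ", "), "), success = ",
        x$success, "\n", sep = "")
  invisible(x)
}
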