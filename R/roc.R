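## ROC evaluation for the recovery of SNPs jointly associated with both
## phenotypes.  A SNP is "called" at a threshold only if it is selected
## for BOTH phenotypes.

#' Wrap per-phenotype scores as a method output
#'
#' @param score1,score2 length-p score vectors (p-values or coefficient
#'   magnitudes) for phenotypes 1 and 2.
#' @param direction `"smaller"` when a smaller score is stronger
#'   evidence (p-values), `"larger"` for coefficient magnitudes.
#' @param label method label.
#' @return An object of class `MethodOutput`.
#' @export
method_output <- function(score1, score2, direction = c("smaller", "larger"),
                          label = "method") {
  direction <- match.arg(direction)
  stopifnot(length(score1) == length(score2),
            all(is.finite(score1)), all(is.finite(score2)))
  structure(list(score1 = as.numeric(score1), score2 = as.numeric(score2),
                 direction = direction, label = label),
            class = "MethodOutput")
}

#' Wrap a regularization path's selections as a method output
#'
#' @param sel1,sel2 `L x p` logical matrices: selection indicators per
#'   hyperparameter (rows) and SNP (columns) for each phenotype.
#' @param label method label.
#' @return An object of class `SelectionPath`.
#' @export
selection_path <- function(sel1, sel2, label = "path") {
  sel1 <- as.matrix(sel1); sel2 <- as.matrix(sel2)
  stopifnot(identical(dim(sel1), dim(sel2)))
  structure(list(sel1 = sel1, sel2 = sel2, label = label),
            class = "SelectionPath")
}

.roc_points_from_calls <- function(calls, common, p) {
  # calls: list of logical vectors (called set per threshold)
  n_pos <- length(common)
  n_neg <- p - n_pos
  tpr <- vapply(calls, function(cl) sum(cl[common]) / n_pos, numeric(1))
  fpr <- vapply(calls, function(cl) (sum(cl) - sum(cl[common])) / n_neg,
                numeric(1))
  pts <- unique(data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  pts
}

.trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC for the recovery of jointly associated SNPs
#'
#' For a score-based method ([method_output()]), a SNP is called at
#' threshold `c` if its score passes `c` in *both* phenotypes, which is
#' equivalent to thresholding the per-SNP combined score (worst of the
#' two).  The full sweep over all distinct combined scores is used.
#' For a path-based method ([selection_path()]), each hyperparameter
#' contributes one (FPR, TPR) point from the intersection of the two
#' selection sets.  Endpoints (0,0) and (1,1) are added, points sorted
#' by FPR, and the AUC computed by the trapezoid rule.
#'
#' @param method a [method_output()] or [selection_path()].
#' @param truth a `SimulationTruth` (its `common` set is used) or an
#'   integer vector of common SNP indices.
#' @param p panel size; required when `truth` is a bare index vector
#'   and ignored otherwise.
#' @return list with `fpr`, `tpr`, `auc`, `label`, and for score-based
#'   methods the combined `score` vector.
#' @export
roc_for_common_snps <- function(method, truth, p = NULL) {
  common <- if (inherits(truth, "SimulationTruth")) truth$common else
    as.integer(truth)
  if (length(common) == 0) stop("truth has no common SNPs")

  if (inherits(method, "MethodOutput")) {
    p <- length(method$score1)
    if (method$direction == "smaller") {
      s <- pmax(method$score1, method$score2)   # called iff both <= c
      thr <- sort(unique(s))
      calls <- lapply(thr, function(cc) s <= cc)
    } else {
      s <- pmin(method$score1, method$score2)   # called iff both >= c
      thr <- sort(unique(s), decreasing = TRUE)
      calls <- lapply(thr, function(cc) s >= cc)
    }
    pts <- .roc_points_from_calls(calls, common, p)
    return(list(fpr = pts$fpr, tpr = pts$tpr,
                auc = .trapezoid_auc(pts$fpr, pts$tpr),
                label = method$label, score = s))
  }
  if (inherits(method, "SelectionPath")) {
    p <- ncol(method$sel1)
    calls <- lapply(seq_len(nrow(method$sel1)),
                    function(i) method$sel1[i, ] & method$sel2[i, ])
    pts <- .roc_points_from_calls(calls, common, p)
    return(list(fpr = pts$fpr, tpr = pts$tpr,
                auc = .trapezoid_auc(pts$fpr, pts$tpr),
                label = method$label))
  }
  stop("method must be a MethodOutput or SelectionPath")
}

#' Hyperparameter grid for path methods
#'
#' Log-spaced penalties spanning `[1e-5, 1e5]`; the simulation study
#' uses 200 points at full scale, fewer at desk scale.
#'
#' @param n_points number of grid points.
#' @return decreasing numeric vector (warm-start friendly).
#' @export
lambda_path <- function(n_points = 200L) {
  sort(exp(seq(log(1e-5), log(1e5), length.out = n_points)),
       decreasing = TRUE)
}
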