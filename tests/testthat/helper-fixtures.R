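# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# a small deterministic raw-dosage study
make_study <- function(n = 6, p = 4, seed = 1, y = NULL, binary = TRUE,
                       ids = NULL, chrom = "1") {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  if (is.null(ids)) ids <- paste0("rs", seq_len(p))
  v <- data.frame(id = ids, chrom = chrom, pos = seq_len(p) * 10L,
                  allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  if (is.null(y)) y <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  genotype_study(X, sprintf("s%03d", seq_len(n)), v, y)
}

# a standardized paired study with iid noise phenotypes
make_paired_gaussian <- function(n = 40, p = 20, seed = 1) {
  set.seed(seed)
  mk <- function(off) {
    X <- matrix(rnorm(n * p), n, p)
    v <- data.frame(id = paste0("rs", seq_len(p)), chrom = "1",
                    pos = seq_len(p) * 10L, allele1 = "A", allele2 = "G",
                    stringsAsFactors = FALSE)
    X <- scale(X, center = TRUE, scale = FALSE)
    X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
    attr(X, "standardized") <- TRUE
    st <- genotype_study(X, sprintf("%s%03d", off, seq_len(n)), v,
                         rnorm(n))
    st
  }
  paired_study(mk("a"), mk("b"))
}

# flat variance components for solver tests
flat_vc <- function(u = 0.1, v = 0.1) variance_components(u, u, v, v)

# independent plain-lasso oracle: slow, simple coordinate descent written
# directly from the subgradient conditions (kept free of package code
# paths; used to cross-check the compiled solver)
oracle_lasso <- function(X, y, w, lambda, max_iter = 5000, tol = 1e-12) {
  p <- ncol(X)
  beta <- numeric(p)
  r <- y
  css <- colSums(X^2)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (css[j] == 0) next
      zj <- 2 * w * (sum(X[, j] * r) + css[j] * beta[j])
      bj <- sign(zj) * max(abs(zj) - lambda, 0) / (2 * w * css[j])
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  beta
}

lasso_objective <- function(X, y, beta, w, lambda) {
  w * sum((y - X %*% beta)^2) + lambda * sum(abs(beta))
}

# lighter solver configuration for simulation-heavy tests (desk scale)
light_config <- function(...) {
  args <- utils::modifyList(
    list(max_admm = 150L, admm_tol = 1e-4, max_outer = 20L), list(...))
  do.call(solver_config, args)
}
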