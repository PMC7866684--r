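#' Construct a GenotypeStudy
#'
#' A `GenotypeStudy` bundles one cohort's genotype dosage matrix, its
#' variant metadata, and the single observed phenotype.  Dosages count
#' copies of `allele1` (the minor allele under PLINK convention), so
#' entries lie in `[0, 2]` after imputation.
#'
#' @param X numeric matrix, `n` samples by `p` SNPs, minor-allele dosages.
#' @param sample_ids character vector of length `n`, unique sample ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based
#'   bp), `allele1`, `allele2`; one row per column of `X`.
#' @param y numeric phenotype vector of length `n`; binary phenotypes are
#'   coded 0/1, missing as `NA`.
#' @param phenotype_name single string naming the phenotype.
#'
#' @return An object of class `GenotypeStudy`.
#' @export
genotype_study <- function(X, sample_ids, variants, y,
                           phenotype_name = "phenotype") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(is.data.frame(variants))
  required <- c("id", "chrom", "pos", "allele1", "allele2")
  if (!all(required %in% names(variants)))
    stop("variants must have columns: ", paste(required, collapse = ", "))
  if (nrow(X) != length(sample_ids))
    stop("row count of X (", nrow(X), ") != number of sample ids (",
         length(sample_ids), ")")
  if (nrow(X) != length(y))
    stop("row count of X (", nrow(X), ") != length of y (", length(y), ")")
  if (ncol(X) != nrow(variants))
    stop("column count of X (", ncol(X), ") != number of variants (",
         nrow(variants), ")")
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique within a study")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique within a study")
  rng <- range(X, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 - 1e-9 || rng[2] > 2 + 1e-9)) {
    # raw dosages live in [0,2]; standardized copies carry an attribute
    if (!isTRUE(attr(X, "standardized")))
      stop("dosage entries must lie in [0, 2] (got range ",
           rng[1], "..", rng[2], ")")
  }
  variants$id <- as.character(variants$id)
  structure(
    list(X = X,
         sample_ids = as.character(sample_ids),
         variants = variants,
         y = as.numeric(y),
         phenotype_name = as.character(phenotype_name)[1]),
    class = "GenotypeStudy")
}

#' @export
print.GenotypeStudy <- function(x, ...) {
  cat("GenotypeStudy: ", nrow(x$X), " samples x ", ncol(x$X), " SNPs\n",
      sep = "")
  cat("  phenotype: ", x$phenotype_name,
      if (all(x$y %in% c(0, 1, NA))) " (binary)" else " (continuous)",
      "\n", sep = "")
  std <- isTRUE(attr(x$X, "standardized"))
  cat("  genotypes: ", if (std) "standardized" else "raw dosages", "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.GenotypeStudy <- function(x) dim(x$X)

#' Construct a PairedStudy
#'
#' Two `GenotypeStudy` objects restricted to an identical, identically
#' ordered SNP panel.  This is the input unit of the coupled mixed model:
#' study 1 observes phenotype 1 only, study 2 observes phenotype 2 only.
#'
#' @param study1,study2 `GenotypeStudy` objects on the same variant panel.
#' @return An object of class `PairedStudy` with fields `study1`,
#'   `study2` and `common_snp_ids`.
#' @export
paired_study <- function(study1, study2) {
  stopifnot(inherits(study1, "GenotypeStudy"), inherits(study2, "GenotypeStudy"))
  if (ncol(study1$X) < 1L) stop("paired studies need at least one SNP")
  if (!identical(study1$variants$id, study2$variants$id))
    stop("studies must share an identical, identically ordered SNP panel")
  structure(
    list(study1 = study1, study2 = study2,
         common_snp_ids = study1$variants$id),
    class = "PairedStudy")
}

#' @export
print.PairedStudy <- function(x, ...) {
  cat("PairedStudy: ", length(x$common_snp_ids), " common SNPs\n", sep = "")
  cat("  study 1 (", x$study1$phenotype_name, "): ",
      nrow(x$study1$X), " samples\n", sep = "")
  cat("  study 2 (", x$study2$phenotype_name, "): ",
      nrow(x$study2$X), " samples\n", sep = "")
  invisible(x)
}
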