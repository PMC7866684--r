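## PLINK 1.9 binary triple (BED/BIM/FAM) input and a minimal writer used
## by the synthetic-data generator, plus SNP-panel harmonization and
## genotype standardization.

# two-bit PLINK codes, LSB-first within each byte:
#   00 -> 2 copies of allele1, 10 -> het, 11 -> 0 copies, 01 -> missing
.plink_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

#' Read a PLINK binary study
#'
#' Reads a `prefix.bed` / `prefix.bim` / `prefix.fam` triple (SNP-major
#' BED) into a [genotype_study()].  Dosages count copies of the BIM
#' `allele1`.  FAM phenotype codes 1/2 are recoded to 0/1 (control/case),
#' and -9/0 to missing; any other numeric value is kept as a continuous
#' phenotype.  Missing genotypes are imputed to the per-SNP mean dosage;
#' SNPs missing in every sample are dropped with a warning.
#'
#' @param prefix path stem; the three files `prefix.bed`, `prefix.bim`,
#'   `prefix.fam` must exist.
#' @param phenotype_name label stored in the study (default: basename of
#'   `prefix`).
#' @return A [genotype_study()].
#' @export
read_plink <- function(prefix, phenotype_name = basename(prefix)) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (pth in paths)
    if (!file.exists(pth)) stop("missing PLINK file: ", pth)

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "character"))
  if (ncol(fam) < 6) stop("FAM file must have 6 columns: ", paths[3])
  sample_ids <- fam[[2]]
  if (anyDuplicated(sample_ids))
    sample_ids <- paste(fam[[1]], fam[[2]], sep = ":")
  pheno_raw <- suppressWarnings(as.numeric(fam[[6]]))
  if (any(is.na(pheno_raw) & !fam[[6]] %in% c("NA", "na")))
    stop("non-numeric phenotype in FAM file: ", paths[3])
  y <- pheno_raw
  if (all(pheno_raw %in% c(-9, 0, 1, 2, NA))) {
    # case/control coding
    y <- ifelse(pheno_raw %in% c(-9, 0), NA, pheno_raw - 1)
  }

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  n <- length(sample_ids)
  p <- nrow(bim)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported: ", paths[1])
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) < bytes_per_snp * p)
    stop("BED file truncated: ", paths[1])

  # decode all two-bit fields at once
  m <- matrix(as.integer(body[seq_len(bytes_per_snp * p)]),
              nrow = bytes_per_snp, ncol = p)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = p)
  for (k in 0:3) {
    codes[seq(k + 1, by = 4, length.out = bytes_per_snp), ] <-
      bitwAnd(m %/% (4L^k), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(.plink_code_to_dosage[as.character(codes)], nrow = n, ncol = p)

  # impute missing genotypes to the per-SNP mean dosage
  all_missing <- integer(0)
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    all_missing <- which(is.nan(cm))
    for (j in which(colSums(is.na(X)) > 0L)) {
      if (j %in% all_missing) next
      X[is.na(X[, j]), j] <- cm[j]
    }
  }
  variants <- bim[, c("id", "chrom", "pos", "allele1", "allele2")]
  if (length(all_missing)) {
    warning("dropping ", length(all_missing),
            " SNP(s) with all genotypes missing: ",
            paste(utils::head(variants$id[all_missing], 5), collapse = ", "))
    X <- X[, -all_missing, drop = FALSE]
    variants <- variants[-all_missing, , drop = FALSE]
    rownames(variants) <- NULL
  }
  genotype_study(X, sample_ids, variants, y, phenotype_name)
}

#' Write a study as a PLINK binary triple
#'
#' Minimal SNP-major BED/BIM/FAM writer.  Dosages must be integral in
#' `{0, 1, 2}` or `NA`; binary phenotypes are written with the PLINK
#' 1/2 control/case convention, `NA` as -9.
#'
#' @param study a [genotype_study()] with raw (unstandardized) dosages.
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(study, prefix) {
  X <- study$X
  n <- nrow(X); p <- ncol(X)
  if (any(abs(X - round(X)) > 1e-9, na.rm = TRUE))
    stop("write_plink needs integral dosages in {0,1,2}")
  # dosage -> two-bit code
  code <- matrix(1L, n, p)              # 01 = missing
  code[!is.na(X) & X == 2] <- 0L
  code[!is.na(X) & X == 1] <- 2L
  code[!is.na(X) & X == 0] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  padded <- matrix(3L, nrow = 4 * bytes_per_snp, ncol = p)  # pad with 11
  padded[seq_len(n), ] <- code
  acc <- padded[seq(1, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    4L * padded[seq(2, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    16L * padded[seq(3, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    64L * padded[seq(4, 4 * bytes_per_snp, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(acc)), con)

  v <- study$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  y <- study$y
  if (all(y %in% c(0, 1, NA))) {
    pheno <- ifelse(is.na(y), -9, y + 1)
  } else {
    pheno <- ifelse(is.na(y), -9, y)
  }
  utils::write.table(
    data.frame(study$sample_ids, study$sample_ids, 0, 0, 0, pheno),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Restrict two studies to their common SNP panel
#'
#' Subsets both studies to the SNP ids present in both, in a
#' deterministic (chromosome, position, id) order, and harmonizes the
#' dosage orientation of study 2: when its allele1/allele2 pair is
#' swapped relative to study 1 the dosage is flipped (`d -> 2 - d`).
#' SNPs whose alleles neither match nor swap are dropped with a warning.
#'
#' @param s1,s2 [genotype_study()] objects.
#' @return A [paired_study()].
#' @export
intersect_snps <- function(s1, s2) {
  common <- intersect(s1$variants$id, s2$variants$id)
  if (length(common) == 0L)
    stop("the two studies share no SNP ids")
  v1 <- s1$variants[match(common, s1$variants$id), ]
  ord <- order(suppressWarnings(as.numeric(v1$chrom)), v1$chrom,
               v1$pos, v1$id, method = "radix")
  common <- common[ord]
  i1 <- match(common, s1$variants$id)
  i2 <- match(common, s2$variants$id)
  a1_1 <- s1$variants$allele1[i1]; a2_1 <- s1$variants$allele2[i1]
  a1_2 <- s2$variants$allele1[i2]; a2_2 <- s2$variants$allele2[i2]
  same <- a1_1 == a1_2 & a2_1 == a2_2
  swap <- a1_1 == a2_2 & a2_1 == a1_2 & !same
  bad <- !(same | swap)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " SNP(s) with irreconcilable alleles: ",
            paste(utils::head(common[bad], 5), collapse = ", "))
    common <- common[!bad]
    i1 <- i1[!bad]; i2 <- i2[!bad]; swap <- swap[!bad]
    if (length(common) == 0L)
      stop("no SNPs left after dropping allele mismatches")
  }
  X1 <- s1$X[, i1, drop = FALSE]
  X2 <- s2$X[, i2, drop = FALSE]
  if (any(swap)) X2[, swap] <- 2 - X2[, swap]
  v1 <- s1$variants[i1, , drop = FALSE]
  rownames(v1) <- NULL
  v2 <- v1
  st1 <- genotype_study(X1, s1$sample_ids, v1, s1$y, s1$phenotype_name)
  st2 <- genotype_study(X2, s2$sample_ids, v2, s2$y, s2$phenotype_name)
  paired_study(st1, st2)
}

#' Column-standardize genotype dosages
#'
#' Centers every SNP column to mean zero and scales polymorphic columns
#' to unit variance (population denominator `n`).  Monomorphic columns
#' become all-zero and are flagged in the `monomorphic` attribute of the
#' returned matrix.  Standardization makes the kinship matrix and the
#' l1 penalties scale-free; it is idempotent.
#'
#' @param study a [genotype_study()] without missing values.
#' @return The study with `X` replaced by its standardized version; the
#'   matrix carries attributes `standardized = TRUE` and `monomorphic`
#'   (logical vector over SNPs).
#' @export
standardize <- function(study) {
  X <- study$X
  if (anyNA(X)) stop("standardize requires imputed (non-missing) genotypes")
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  v <- colMeans(Xc^2)                  # population variance
  mono <- v <= 1e-12
  sdv <- sqrt(ifelse(mono, 1, v))
  Xs <- sweep(Xc, 2, sdv, "/")
  Xs[, mono] <- 0
  attr(Xs, "standardized") <- TRUE
  attr(Xs, "monomorphic") <- mono
  out <- study
  out$X <- Xs
  out
}
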