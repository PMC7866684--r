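## Synthetic paired-GWAS generator: Balding-Nichols population
## structure, kinship-driven and collection (batch) confounders, planted
## causal/common SNPs, and an aggregate signal-to-noise calibration.

#' Simulation configuration
#'
#' The stated world of the simulation study: two independently collected
#' case/control cohorts typed on one SNP panel, with population
#' stratification (Balding-Nichols differentiation `fst` across
#' `n_pop` subpopulations mixed differently in the two cohorts),
#' kinship-driven confounding of variance `sigma_u_sq`, cohort-specific
#' iid collection confounding of variance `sigma_v_sq`, and sparse
#' genetic effects calibrated so the aggregate effect-size
#' signal-to-noise ratio `Var(X beta) / Var(u + v)` is `target_snr`
#' (0.25 by default).
#'
#' @param n samples per data set.
#' @param p number of SNPs.
#' @param n_pop number of subpopulations.
#' @param fst differentiation parameter in (0, 1).
#' @param maf_range ancestral minor-allele-frequency interval.
#' @param frac_causal fraction of SNPs causal per phenotype.
#' @param frac_common fraction of causal SNPs shared between phenotypes.
#' @param target_snr aggregate signal-to-noise target (> 0).
#' @param sigma_u_sq,sigma_v_sq confounder variances.
#' @param binary generate case/control phenotypes by median-thresholding
#'   the liability (balanced); `FALSE` keeps the continuous liability.
#' @param seed integer master seed; all substreams derive from it.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(n = 500L, p = 5000L, n_pop = 3L, fst = 0.1,
                              maf_range = c(0.05, 0.5),
                              frac_causal = 0.005, frac_common = 0.5,
                              target_snr = 0.25,
                              sigma_u_sq = 1.0, sigma_v_sq = 1.0,
                              binary = TRUE, seed = 1L) {
  stopifnot(n >= 2, p >= 1, n_pop >= 1, fst > 0, fst < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            frac_causal * p >= 1, frac_common >= 0, frac_common <= 1,
            target_snr > 0, sigma_u_sq >= 0, sigma_v_sq >= 0)
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_pop = as.integer(n_pop), fst = fst,
                 maf_range = maf_range, frac_causal = frac_causal,
                 frac_common = frac_common, target_snr = target_snr,
                 sigma_u_sq = sigma_u_sq, sigma_v_sq = sigma_v_sq,
                 binary = isTRUE(binary), seed = as.integer(seed)),
            class = "SimulationConfig")
}

.std_mat <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  v <- colMeans(Xc^2)
  mono <- v <= 1e-12
  Xs <- sweep(Xc, 2, sqrt(ifelse(mono, 1, v)), "/")
  Xs[, mono] <- 0
  attr(Xs, "monomorphic") <- mono
  Xs
}

# draw one cohort's dosages given per-subpopulation allele frequencies
.draw_cohort <- function(n, freqs, mixture) {
  n_pop <- nrow(freqs); p <- ncol(freqs)
  sizes <- floor(n * mixture)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  pop <- rep.int(seq_len(n_pop), sizes)
  X <- matrix(0L, n, p)
  for (k in seq_len(n_pop)) {
    idx <- which(pop == k)
    X[idx, ] <- matrix(stats::rbinom(length(idx) * p, 2L,
                                     rep(freqs[k, ], each = length(idx))),
                       nrow = length(idx))
  }
  list(X = X, pop = pop)
}

#' Simulate structured genotypes for two cohorts
#'
#' Balding-Nichols scheme: ancestral frequency `f_j ~ U(maf_range)`;
#' subpopulation `k` frequency `~ Beta(f_j (1-fst)/fst,
#' (1-f_j)(1-fst)/fst)`; dosages `~ Binomial(2, freq)`.  The two cohorts
#' share the subpopulation allele frequencies (same panel) but mix the
#' subpopulations in different proportions — cohort 1 equally, cohort 2
#' with a linearly skewed mixture — emulating independent collection.
#' A SNP that comes out monomorphic in a cohort is resampled once, then
#' kept with a warning.
#'
#' @param config a [simulation_config()].
#' @return list with dosage matrices `X1`, `X2`, subpopulation labels
#'   `pop1`, `pop2`, and the `n_pop x p` frequency matrix `freqs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(.substream(config$seed, "genotypes"), {
    p <- config$p; n_pop <- config$n_pop; fst <- config$fst
    f <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    a <- f * (1 - fst) / fst
    b <- (1 - f) * (1 - fst) / fst
    freqs <- matrix(stats::rbeta(n_pop * p, rep(a, each = n_pop),
                                 rep(b, each = n_pop)),
                    nrow = n_pop)
    mix1 <- rep(1 / n_pop, n_pop)
    mix2 <- if (n_pop == 1) 1 else {
      w <- seq(1, 2, length.out = n_pop); w / sum(w)
    }
    c1 <- .draw_cohort(config$n, freqs, mix1)
    c2 <- .draw_cohort(config$n, freqs, mix2)
    for (nm in c("c1", "c2")) {
      co <- get(nm)
      v <- apply(co$X, 2, stats::var)
      mono <- which(v == 0)
      if (length(mono)) {
        # resample monomorphic columns once
        for (j in mono) {
          fr <- freqs[co$pop, j]
          co$X[, j] <- stats::rbinom(config$n, 2L, fr)
        }
        still <- mono[apply(co$X[, mono, drop = FALSE], 2, stats::var) == 0]
        if (length(still))
          warning(length(still), " SNP(s) monomorphic in a cohort after resampling")
        assign(nm, co)
      }
    }
    list(X1 = c1$X, X2 = c2$X, pop1 = c1$pop, pop2 = c2$pop, freqs = freqs)
  })
}

#' Simulate a paired study with planted causal SNPs
#'
#' Draws causal index sets honoring `frac_causal` and `frac_common`
#' (shared SNPs get *identical* effect values in both phenotypes),
#' builds liabilities `l = X beta + u + v` on the standardized genotype
#' scale with `u ~ N(0, sigma_u_sq K)` (kinship from the cohort's own
#' standardized genotypes) and `v ~ N(0, sigma_v_sq I)` (one draw per
#' cohort, shared by both phenotypes), and rescales the effect vectors
#' by one shared multiplier so that the mean over the two observed
#' phenotypes of `Var(X beta) / Var(u + v)` equals `target_snr` exactly.
#' Binary phenotypes threshold the liability at its median (balanced
#' cases/controls).
#'
#' Only `y1^(1)` and `y2^(2)` are observed in the returned
#' [paired_study()] (raw dosages, ready for the PLINK round trip); the
#' unobserved cross-phenotypes and all ground truth live in the
#' `SimulationTruth` object.
#'
#' @param config a [simulation_config()].
#' @param genotypes optional precomputed [simulate_genotypes()] result.
#' @return list with `paired` (a [paired_study()]) and `truth`
#'   (class `SimulationTruth`: `causal1`, `causal2`, `common`,
#'   `effects1`, `effects2`, `realized_snr1`, `realized_snr2`,
#'   `y1_pheno2`, `y2_pheno1`, `liability`, `pop1`, `pop2`).
#' @export
simulate_paired_study <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$sigma_u_sq == 0 && config$sigma_v_sq == 0)
    stop("sigma_u_sq = sigma_v_sq = 0: the effect-size signal-to-noise ",
         "ratio Var(X beta)/Var(u + v) is undefined")
  p <- config$p; n <- config$n
  # round half up so e.g. 25 causal at frac_common 0.5 share 13
  n_causal <- floor(config$frac_causal * p + 0.5)
  n_common <- floor(config$frac_common * n_causal + 0.5)
  if (config$frac_common > 0 && n_common < 1)
    stop("frac_common * frac_causal * p < 1: no common SNP representable")

  if (is.null(genotypes)) genotypes <- simulate_genotypes(config)
  X1s <- .std_mat(genotypes$X1)
  X2s <- .std_mat(genotypes$X2)

  .with_seed(.substream(config$seed, "effects"), {
    idx_common <- sort(sample.int(p, n_common))
    rest <- setdiff(seq_len(p), idx_common)
    n_spec <- n_causal - n_common
    spec <- sample(rest, 2 * n_spec)
    causal1 <- sort(c(idx_common, spec[seq_len(n_spec)]))
    causal2 <- sort(c(idx_common, spec[n_spec + seq_len(n_spec)]))
    b1 <- numeric(p); b2 <- numeric(p)
    b1[causal1] <- stats::rnorm(n_causal)
    b2[causal2] <- stats::rnorm(n_causal)
    shared_vals <- stats::rnorm(n_common)
    b1[idx_common] <- shared_vals          # identical effect on common SNPs
    b2[idx_common] <- shared_vals

    # confounders: u per (cohort, phenotype), v once per cohort
    draw_u <- function(Xs) {
      K <- tcrossprod(Xs) / ncol(Xs)
      eg <- eigen(K, symmetric = TRUE)
      d <- pmax(eg$values, 0)
      function() sqrt(config$sigma_u_sq) *
        drop(eg$vectors %*% (sqrt(d) * stats::rnorm(n)))
    }
    ru1 <- draw_u(X1s); ru2 <- draw_u(X2s)
    u1_p1 <- ru1(); u1_p2 <- ru1()
    u2_p1 <- ru2(); u2_p2 <- ru2()
    v1 <- sqrt(config$sigma_v_sq) * stats::rnorm(n)
    v2 <- sqrt(config$sigma_v_sq) * stats::rnorm(n)

    g1 <- drop(X1s %*% b1)                 # genetic values, observed pairs
    g2 <- drop(X2s %*% b2)
    noise11 <- u1_p1 + v1
    noise22 <- u2_p2 + v2
    pvar <- function(x) mean((x - mean(x))^2)
    r11 <- pvar(g1) / pvar(noise11)
    r22 <- pvar(g2) / pvar(noise22)
    # one shared multiplier keeps common effects identical across
    # phenotypes while the mean observed SNR hits the target exactly
    cmult <- sqrt(2 * config$target_snr / (r11 + r22))
    b1 <- cmult * b1; b2 <- cmult * b2
    realized_snr1 <- cmult^2 * r11
    realized_snr2 <- cmult^2 * r22

    lia <- list(
      l1_p1 = cmult * g1 + noise11,
      l1_p2 = drop(X1s %*% b2) + u1_p2 + v1,
      l2_p1 = drop(X2s %*% b1) + u2_p1 + v2,
      l2_p2 = cmult * g2 + noise22)
    binz <- function(l) as.numeric(l > stats::median(l))
    y1 <- if (config$binary) binz(lia$l1_p1) else lia$l1_p1
    y2 <- if (config$binary) binz(lia$l2_p2) else lia$l2_p2

    variants <- data.frame(
      id = sprintf("snp%06d", seq_len(p)), chrom = "1",
      pos = seq_len(p) * 1000L,
      allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
    st1 <- genotype_study(genotypes$X1, sprintf("s1_%04d", seq_len(n)),
                          variants, y1, "phenotype1")
    st2 <- genotype_study(genotypes$X2, sprintf("s2_%04d", seq_len(n)),
                          variants, y2, "phenotype2")
    truth <- structure(
      list(causal1 = causal1, causal2 = causal2, common = idx_common,
           effects1 = b1, effects2 = b2,
           realized_snr1 = realized_snr1, realized_snr2 = realized_snr2,
           y1_pheno2 = if (config$binary) binz(lia$l1_p2) else lia$l1_p2,
           y2_pheno1 = if (config$binary) binz(lia$l2_p1) else lia$l2_p1,
           liability = lia,
           pop1 = genotypes$pop1, pop2 = genotypes$pop2,
           snr_definition = "Var(X beta) / Var(u + v), liability scale",
           config = config),
      class = "SimulationTruth")
    list(paired = paired_study(st1, st2), truth = truth)
  })
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth: ", length(x$causal1), " causal per phenotype, ",
      length(x$common), " common\n", sep = "")
  cat(sprintf("  realized SNR: %.3f / %.3f (target %.3f)\n",
              x$realized_snr1, x$realized_snr2, x$config$target_snr))
  invisible(x)
}

#' Write a simulated paired study to disk
#'
#' Writes each cohort as a PLINK BED/BIM/FAM triple plus a JSON ground
#' truth file, so the full pipeline can be exercised through the real
#' I/O path.
#'
#' @param sim a [simulate_paired_study()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name stem (default "study").
#' @return Named character vector of the two PLINK prefixes and the
#'   truth path, invisibly.
#' @export
write_paired_study <- function(sim, dir, prefix = "study") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "1"))
  p2 <- file.path(dir, paste0(prefix, "2"))
  write_plink(sim$paired$study1, p1)
  write_plink(sim$paired$study2, p2)
  tr <- sim$truth
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(
    list(causal1 = tr$causal1, causal2 = tr$causal2, common = tr$common,
         effects1 = tr$effects1, effects2 = tr$effects2,
         realized_snr1 = tr$realized_snr1, realized_snr2 = tr$realized_snr2,
         snr_definition = tr$snr_definition,
         config = unclass(tr$config)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(prefix1 = p1, prefix2 = p2, truth = truth_path))
}
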