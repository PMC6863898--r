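# Synthetic case-control genotype data with LD-block structure and a
# liability-threshold phenotype.  The generator exists so that the whole
# region-scan pipeline (windowing, sparse probit MCMC, permutation testing,
# validation, consensus) can be exercised end-to-end without access to
# controlled genotype repositories.

#' Specify one LD block of SNPs
#'
#' A block is a run of adjacent SNPs whose haplotype alleles share a latent
#' exchangeable Gaussian correlation \code{rho} (Gaussian copula); SNPs in
#' different blocks are independent.  Per-SNP minor-allele frequencies are
#' drawn uniformly from \code{maf_range}.
#'
#' @param n_snps number of SNPs in the block (>= 1).
#' @param rho latent within-block correlation, in \code{[0, 1)}.
#' @param maf_range length-2 numeric, minor-allele frequency bounds in
#'   \code{(0, 0.5]}; a single value is recycled to both bounds.
#' @param corr correlation structure: \code{"exchangeable"} (default) or
#'   \code{"ar1"} (correlation \code{rho^|j-k|} between latent variables).
#' @return a \code{"block_spec"} list.
#' @export
block_spec <- function(n_snps, rho = 0, maf_range = c(0.05, 0.5),
                       corr = c("exchangeable", "ar1")) {
  corr <- match.arg(corr)
  if (length(maf_range) == 1L) maf_range <- c(maf_range, maf_range)
  if (n_snps < 1L) stop_input("block must contain at least one SNP")
  if (rho < 0 || rho >= 1) stop_input("rho must be in [0, 1)")
  if (maf_range[1L] > maf_range[2L])
    stop_input("maf_range lower bound exceeds upper bound")
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5)
    stop_input("minor-allele frequencies must lie in (0, 0.5]")
  structure(list(n_snps = as.integer(n_snps), rho = rho,
                 maf_range = maf_range, corr = corr),
            class = "block_spec")
}

# Draw a (2*n_subjects) x n_snps matrix of 0/1 haplotype alleles for one block.
sample_block_haplotypes <- function(n_hap, spec, mafs) {
  m <- spec$n_snps
  if (spec$corr == "exchangeable") {
    shared <- stats::rnorm(n_hap)
    eps <- matrix(stats::rnorm(n_hap * m), n_hap, m)
    u <- sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * eps
  } else {
    u <- matrix(0, n_hap, m)
    u[, 1L] <- stats::rnorm(n_hap)
    if (m > 1L) {
      s <- sqrt(1 - spec$rho^2)
      for (j in 2:m) u[, j] <- spec$rho * u[, j - 1L] + s * stats::rnorm(n_hap)
    }
  }
  # allele = minor allele iff the latent Gaussian is below the MAF quantile
  u < matrix(stats::qnorm(mafs), n_hap, m, byrow = TRUE)
}

#' Simulate genotype dosages with LD-block structure
#'
#' Each subject receives two independent haplotypes; within a block the
#' haplotype alleles are generated by thresholding a latent Gaussian with the
#' block's correlation at the quantile matching each SNP's minor-allele
#' frequency, so dosages are 0/1/2 and adjacent SNPs are correlated the way
#' genotyping-array data are.  Base-pair positions are synthetic and evenly
#' spaced; only their ordering and distances matter downstream.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param layout named list: one element per chromosome (names are the
#'   chromosome labels, must be distinct), each a list of [block_spec()]s.
#' @param bp_start first SNP position on each chromosome.
#' @param bp_step spacing between adjacent SNP positions (>= 1).
#' @param seed integer seed; the generator is fully reproducible.
#' @return a [genotype_matrix()], minor-allele oriented, with no missing
#'   entries and \code{snp_variance} filled.
#' @export
simulate_genotypes <- function(n_subjects, layout, bp_start = 100000L,
                               bp_step = 5000L, seed = 1L) {
  if (n_subjects < 2L) stop_input("need at least two subjects")
  if (!length(layout)) stop_input("layout is empty")
  chroms <- names(layout)
  if (is.null(chroms) || any(!nzchar(chroms)) || anyDuplicated(chroms))
    stop_input("layout must be a named list with distinct chromosome labels")
  if (bp_step < 1L) stop_input("bp_step must be >= 1")

  with_seed(seed, {
    dos_list <- list(); meta_list <- list()
    for (ch in chroms) {
      blocks <- layout[[ch]]
      if (inherits(blocks, "block_spec")) blocks <- list(blocks)
      off <- 0L
      for (b in seq_along(blocks)) {
        spec <- blocks[[b]]
        if (!inherits(spec, "block_spec")) stop_input("layout entries must be block_spec objects")
        mafs <- stats::runif(spec$n_snps, spec$maf_range[1L], spec$maf_range[2L])
        hap <- sample_block_haplotypes(2L * n_subjects, spec, mafs)
        d <- hap[seq_len(n_subjects), , drop = FALSE] +
             hap[n_subjects + seq_len(n_subjects), , drop = FALSE]
        dos_list[[length(dos_list) + 1L]] <- d
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          snp_id = sprintf("chr%s_s%d", ch, off + seq_len(spec$n_snps)),
          chrom = ch,
          pos = bp_start + bp_step * (off + seq_len(spec$n_snps) - 1L),
          minor = "A", major = "G", stringsAsFactors = FALSE)
        off <- off + spec$n_snps
      }
    }
    G <- genotype_matrix(do.call(cbind, dos_list), do.call(rbind, meta_list))
    orient_minor_allele(G)
  })
}

#' Simulate a binary phenotype under the liability-threshold model
#'
#' Liability is \eqn{\sum_j \beta_j \tilde x_j + \epsilon} with standard
#' normal noise, the \eqn{\tilde x_j} empirically standardised dosages of the
#' causal SNPs, and each \eqn{\beta_j} sized so that that SNP contributes the
#' fraction \code{per_variant_h} of the liability variance (the default,
#' 0.0017, is the scale of a single locus of a highly polygenic trait where
#' around a hundred loci jointly explain under a fifth of variance).  A
#' subject is a case iff liability exceeds the quantile matching
#' \code{prevalence}.  With \code{balanced = TRUE} subjects are subsampled to
#' equal case and control counts, emulating a balanced case-control design.
#'
#' @param G a [genotype_matrix()] with no missing entries.
#' @param n_causal number of causal SNPs (may be 0 for a null phenotype).
#' @param per_variant_h liability-variance fraction per causal SNP, in
#'   \code{[0, 1)}; \code{n_causal * per_variant_h} must be < 1.
#' @param prevalence population case probability, in (0, 1).
#' @param balanced subsample to cases == controls?
#' @param seed integer seed.
#' @param causal_indices optional SNP column indices; drawn uniformly without
#'   replacement when NULL.
#' @return list with \code{phenotype} (a [phenotype_vector()]),
#'   \code{subjects} (indices into \code{G} of the retained subjects; all
#'   subjects unless \code{balanced}), and \code{truth}, a
#'   \code{"synthetic_truth"} list (\code{causal_indices}, \code{snp_id},
#'   \code{effects}, \code{per_variant_h}, \code{prevalence}).
#' @export
simulate_phenotype <- function(G, n_causal, per_variant_h = 0.0017,
                               prevalence = 0.01, balanced = FALSE,
                               seed = 1L, causal_indices = NULL) {
  p <- n_snps(G); n <- n_subjects(G)
  if (anyNA(G$dosages)) stop_input("genotypes contain missing entries; impute first")
  if (n_causal > p) stop_input("n_causal (%d) exceeds SNP count (%d)", n_causal, p)
  if (per_variant_h < 0 || per_variant_h >= 1)
    stop_input("per_variant_h must be in [0, 1)")
  if (n_causal * per_variant_h >= 1)
    stop_input("total variance explained n_causal * per_variant_h must be < 1")
  if (prevalence <= 0 || prevalence >= 1)
    stop_input("prevalence must be in (0, 1)")

  with_seed(seed, {
    if (is.null(causal_indices)) {
      causal_indices <- sort(sample.int(p, n_causal))
    } else {
      causal_indices <- sort(as.integer(causal_indices))
      if (length(causal_indices) != n_causal)
        stop_input("causal_indices length != n_causal")
      if (any(causal_indices < 1L | causal_indices > p))
        stop_input("causal_indices out of range")
    }
    # |beta|^2 = h / (1 - C h) makes each marginal contribution h of the
    # total liability variance C |beta|^2 + 1 (cross-covariances ignored).
    if (n_causal > 0L && per_variant_h > 0) {
      b2 <- per_variant_h / (1 - n_causal * per_variant_h)
      beta <- sqrt(b2) * sample(c(-1, 1), n_causal, replace = TRUE)
      Xc <- scale(G$dosages[, causal_indices, drop = FALSE])
      if (anyNA(Xc)) stop_input("causal SNP with zero variance")
      genetic <- drop(Xc %*% beta)
      liab_var <- n_causal * b2 + 1
    } else {
      beta <- numeric(n_causal)
      genetic <- numeric(n)
      liab_var <- 1
    }
    liability <- genetic + stats::rnorm(n)
    threshold <- stats::qnorm(1 - prevalence, sd = sqrt(liab_var))
    y <- as.integer(liability > threshold)

    subjects <- seq_len(n)
    if (balanced) {
      cases <- which(y == 1L); ctrls <- which(y == 0L)
      k <- min(length(cases), length(ctrls))
      if (k < 1L) stop_input("cannot balance: no %s simulated",
                             if (length(cases)) "controls" else "cases")
      subjects <- sort(c(sample(cases, k), sample(ctrls, k)))
      y <- y[subjects]
    }

    h_each <- if (n_causal > 0L) beta^2 / liab_var else numeric(0)
    truth <- structure(list(
      causal_indices = causal_indices,
      snp_id = G$snp_meta$snp_id[causal_indices],
      effects = beta,
      per_variant_h = h_each,
      prevalence = prevalence
    ), class = "synthetic_truth")
    list(phenotype = phenotype_vector(y), subjects = subjects, truth = truth)
  })
}

#' Mask genotype entries at random
#'
#' Each entry is masked independently with probability \code{rate}, creating
#' the missing-data condition that per-SNP mean imputation later repairs.  A
#' column that ends up fully masked is re-drawn a few times; if it cannot be
#' repaired the call is rejected, since every SNP must keep at least one
#' observed genotype.
#'
#' @param G a [genotype_matrix()].
#' @param rate masking probability in \code{[0, 1)}.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with \code{NA} dosages and the mask recorded
#'   in \code{missing_mask}.
#' @export
inject_missing <- function(G, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop_input("rate must be in [0, 1)")
  if (rate == 0) return(G)
  n <- n_subjects(G); p <- n_snps(G)
  with_seed(seed, {
    mask <- matrix(stats::runif(n * p) < rate, n, p)
    for (j in which(colSums(!mask) == 0L)) {
      for (try in 1:10) {
        mask[, j] <- stats::runif(n) < rate
        if (any(!mask[, j])) break
      }
      if (all(mask[, j]))
        stop_input("cannot keep one observed genotype per SNP at rate %g (SNP %s)",
                   rate, G$snp_meta$snp_id[j])
    }
    dos <- G$dosages
    dos[mask] <- NA_real_
    genotype_matrix(dos, G$snp_meta, G$subject_ids, mask)
  })
}

#' Subset the SNP panel to emulate a second genotyping platform
#'
#' Keeps a uniformly sampled subset of SNP columns (positions and order
#' unchanged), modelling a validation cohort genotyped on a different array
#' whose panel only partially overlaps the discovery panel.  An independent
#' validation cohort itself is obtained by re-running [simulate_genotypes()]
#' with the same layout and a different seed, then subsetting with this
#' function.
#'
#' @param G a [genotype_matrix()].
#' @param keep_fraction fraction of SNPs retained, in \code{(0, 1]}.
#' @param jitter_ids rename kept SNPs with a platform-specific suffix?
#' @param seed integer seed.
#' @return a [genotype_matrix()] with \code{round(keep_fraction * n_snps)}
#'   columns.
#' @export
make_platform_subset <- function(G, keep_fraction, jitter_ids = FALSE,
                                 seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_input("keep_fraction must be in (0, 1]")
  p <- n_snps(G)
  k <- max(1L, round(keep_fraction * p))
  with_seed(seed, {
    keep <- sort(sample.int(p, k))
    out <- subset_snps(G, keep)
    if (jitter_ids)
      out$snp_meta$snp_id <- paste0(out$snp_meta$snp_id, "_p2")
    out
  })
}

#' Write a synthetic-truth table
#'
#' @param truth a \code{"synthetic_truth"} object from [simulate_phenotype()].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(snp_id = truth$snp_id, effect = truth$effects,
               per_variant_h = truth$per_variant_h),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
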