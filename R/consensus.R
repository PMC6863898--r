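# Validation of candidate regions in an independent cohort and the
# cross-dataset LD consensus analysis.  Because validation cohorts are
# genotyped on different platforms, a discovery region is mapped to the
# validation panel by its base-pair interval (both ends inclusive), and the
# mean PIP replaces the sum to account for the variable marker count.

#' Map a discovery region onto a validation SNP panel
#'
#' Returns the validation-panel SNPs on the region's chromosome whose
#' positions fall inside \code{[start_pos, end_pos]}, both ends inclusive.
#'
#' @param region one row of a [partition_genome()] result (a data frame or
#'   list with \code{chrom}, \code{start_pos}, \code{end_pos}).
#' @param validation_meta SNP metadata of the validation panel (the
#'   \code{snp_meta} of its [genotype_matrix()]), sorted by (chrom, pos).
#' @return integer vector of column indices into the validation panel;
#'   empty, with a warning, when the interval contains no validation SNPs or
#'   the chromosome is absent.
#' @export
map_region_to_validation <- function(region, validation_meta) {
  idx <- which(validation_meta$chrom == region$chrom &
               validation_meta$pos >= region$start_pos &
               validation_meta$pos <= region$end_pos)
  if (!length(idx)) {
    if (!any(validation_meta$chrom == region$chrom))
      warning(sprintf("chromosome %s absent from validation panel", region$chrom))
    else
      warning(sprintf("no validation SNPs in [%s, %s] on chromosome %s",
                      format(region$start_pos, scientific = FALSE),
                      format(region$end_pos, scientific = FALSE), region$chrom))
  }
  idx
}

#' Validate candidate regions in an independent cohort
#'
#' Maps each candidate region onto the validation panel by position
#' interval and runs a mean-PIP permutation test there, at the
#' Bonferroni-adjusted level \code{alpha / length(candidates)}.
#'
#' @param candidates a [partition_genome()]-style data frame of candidate
#'   regions (typically the significant rows of a [genomewide_scan()]).
#' @param G_val validation-cohort [genotype_matrix()] (no missing entries).
#' @param y_val validation [phenotype_vector()].
#' @param priors,config as in [run_bvs()].
#' @param B permutations per region (default 1000).
#' @param alpha family-wise error target (default 0.05).
#' @param master_seed integer seed.
#' @return data frame with one row per candidate: \code{chrom},
#'   \code{rank_on_chrom}, \code{start_pos}, \code{end_pos},
#'   \code{n_snps_val}, \code{mean_pip}, \code{p_emp}, \code{p_text},
#'   \code{B_done}, \code{validated}, \code{reason}.
#' @export
validate_regions <- function(candidates, G_val, y_val,
                             priors = bvs_priors(), config = bvs_config(),
                             B = 1000L, alpha = 0.05, master_seed = 1L) {
  if (!nrow(candidates)) stop_input("no candidate regions supplied")
  alpha_adj <- bonferroni_threshold(alpha, nrow(candidates))
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    idx <- suppressWarnings(map_region_to_validation(cand, G_val$snp_meta))
    if (!length(idx)) {
      out[[i]] <- data.frame(
        chrom = cand$chrom, rank_on_chrom = cand$rank_on_chrom,
        start_pos = cand$start_pos, end_pos = cand$end_pos,
        n_snps_val = 0L, mean_pip = NA_real_, p_emp = NA_real_,
        p_text = NA_character_, B_done = 0L, validated = FALSE,
        reason = "no validation SNPs in interval", stringsAsFactors = FALSE)
      next
    }
    pr <- region_permutation_test(
      subset_snps(G_val, idx), y_val, priors, config,
      B_target = B, alpha_adj = alpha_adj, statistic = "mean_pip",
      batch = min(100L, B), master_seed = master_seed, region_tag = i)
    out[[i]] <- data.frame(
      chrom = cand$chrom, rank_on_chrom = cand$rank_on_chrom,
      start_pos = cand$start_pos, end_pos = cand$end_pos,
      n_snps_val = length(idx), mean_pip = pr$observed_stat,
      p_emp = pr$p_emp, p_text = pr$p_text, B_done = pr$B_done,
      validated = pr$significant, reason = NA_character_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha_adj") <- alpha_adj
  res
}

#' Squared dosage correlation between two SNPs
#'
#' The usual genotype-based linkage-disequilibrium measure: the squared
#' Pearson correlation of dosage vectors.  Symmetric, and invariant under
#' the allele flip \code{x -> 2 - x} of either vector.
#'
#' @param dosage_a,dosage_b numeric vectors of equal length >= 3, neither
#'   constant.
#' @return r-squared in \code{[0, 1]}.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop_input("dosage vectors differ in length")
  if (length(dosage_a) < 3L) stop_input("need at least 3 subjects")
  if (stats::sd(dosage_a) == 0 || stats::sd(dosage_b) == 0)
    stop_input("constant dosage vector: r2 undefined")
  stats::cor(dosage_a, dosage_b)^2
}

# Select the top-PIP SNPs of the top-sum-PIP regions of one scan.
# Ties are broken by genomic order for determinism.
top_scan_snps <- function(scan, top_region_frac, top_snp_frac) {
  pips <- attr(scan, "pip_tables")
  if (is.null(pips)) stop_input("scan lacks per-SNP PIP tables")
  n_sel <- ceiling(top_region_frac * nrow(scan))
  reg_ord <- order(-scan$sum_pip, scan$chrom, scan$rank_on_chrom)
  sel <- reg_ord[seq_len(n_sel)]
  out <- lapply(sel, function(i) {
    tab <- pips[[i]]
    k <- ceiling(top_snp_frac * nrow(tab))
    tab[order(-tab$pip, tab$chrom, tab$pos)[seq_len(k)], , drop = FALSE]
  })
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Cross-dataset overlap and LD consensus analysis
#'
#' From each scan, selects the top fraction of regions by sum of PIPs and,
#' within each, the top fraction of SNPs by PIP.  Every selected SNP of one
#' dataset is paired with every selected SNP of the other on the same
#' chromosome within \code{window_bp} (the overlap set, formed symmetrically
#' in both directions and de-duplicated).  For each pair, LD is computed as
#' the squared dosage correlation in a designated reference genotype set
#' containing both SNPs; pairs at or above \code{r2_threshold} form the
#' consensus set.
#'
#' @param scan_a,scan_b [genomewide_scan()] results for the two datasets.
#' @param ld_reference a [genotype_matrix()] containing the selected SNPs of
#'   both panels (in synthetic runs, the full simulated panel).
#' @param top_region_frac fraction of regions selected (default 0.05).
#' @param top_snp_frac fraction of SNPs selected per region (default 0.01,
#'   at least one SNP).
#' @param window_bp pairing distance in base pairs (default 100000).
#' @param r2_threshold LD cutoff declaring a pair "in LD" (default 0.2).
#' @return list with \code{pairs} (data frame: \code{snp_a}, \code{snp_b},
#'   \code{chrom}, \code{distance_bp}, \code{r2}, \code{in_ld}) and
#'   \code{summary} (\code{n_pairs}, \code{n_ld}, \code{pct_in_ld}, counts
#'   of selected SNPs).  Pairs whose r2 is unavailable in the reference are
#'   kept with \code{r2 = NA} but excluded from the percentage denominator.
#' @export
overlap_consensus <- function(scan_a, scan_b, ld_reference,
                              top_region_frac = 0.05, top_snp_frac = 0.01,
                              window_bp = 100000, r2_threshold = 0.2) {
  snps_a <- top_scan_snps(scan_a, top_region_frac, top_snp_frac)
  snps_b <- top_scan_snps(scan_b, top_region_frac, top_snp_frac)

  pairs <- list()
  for (i in seq_len(nrow(snps_a))) {
    hit <- which(snps_b$chrom == snps_a$chrom[i] &
                 abs(snps_b$pos - snps_a$pos[i]) <= window_bp)
    if (length(hit))
      pairs[[length(pairs) + 1L]] <- data.frame(
        snp_a = snps_a$snp_id[i], snp_b = snps_b$snp_id[hit],
        chrom = snps_a$chrom[i],
        distance_bp = abs(snps_b$pos[hit] - snps_a$pos[i]),
        pos_a = snps_a$pos[i], pos_b = snps_b$pos[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    return(list(pairs = data.frame(snp_a = character(), snp_b = character(),
                                   chrom = character(), distance_bp = numeric(),
                                   r2 = numeric(), in_ld = logical()),
                summary = data.frame(n_pairs = 0L, n_ld = 0L,
                                     pct_in_ld = NA_real_,
                                     n_snps_a = nrow(snps_a),
                                     n_snps_b = nrow(snps_b))))
  }
  pairs <- unique(do.call(rbind, pairs))

  # LD in the reference panel: match by SNP id first, fall back to position
  ref_meta <- ld_reference$snp_meta
  locate <- function(id, chrom, pos) {
    j <- match(id, ref_meta$snp_id)
    if (is.na(j)) j <- which(ref_meta$chrom == chrom & ref_meta$pos == pos)[1L]
    j
  }
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    ja <- locate(pairs$snp_a[k], pairs$chrom[k], pairs$pos_a[k])
    jb <- locate(pairs$snp_b[k], pairs$chrom[k], pairs$pos_b[k])
    if (is.na(ja) || is.na(jb)) return(NA_real_)
    da <- ld_reference$dosages[, ja]; db <- ld_reference$dosages[, jb]
    if (stats::sd(da) == 0 || stats::sd(db) == 0) return(NA_real_)
    ld_r2(da, db)
  }, 0)
  if (anyNA(r2))
    message(sprintf("%d pair(s) without usable reference genotypes excluded from the LD percentage",
                    sum(is.na(r2))))
  pairs$r2 <- r2
  pairs$in_ld <- !is.na(r2) & r2 >= r2_threshold
  pairs$pos_a <- pairs$pos_b <- NULL
  n_eval <- sum(!is.na(r2))
  summary <- data.frame(
    n_pairs = nrow(pairs), n_ld = sum(pairs$in_ld),
    pct_in_ld = if (n_eval) 100 * sum(pairs$in_ld) / n_eval else NA_real_,
    n_snps_a = nrow(snps_a), n_snps_b = nrow(snps_b))
  list(pairs = pairs, summary = summary)
}
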