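#' Genotype dosage matrix with SNP metadata
#'
#' Container for a subjects-by-SNPs matrix of minor-allele dosages together
#' with per-SNP metadata (identifier, chromosome, base-pair position, minor
#' and major allele labels), optional missingness mask and per-SNP sample
#' variances.  Dosages count copies of the minor allele, so before any
#' imputation entries are 0, 1 or 2; after mean imputation they are real
#' values in \code{[0, 2]}.
#'
#' @param dosages numeric matrix, subjects in rows, SNPs in columns; values in
#'   \code{[0, 2]} or \code{NA} for missing genotypes.
#' @param snp_meta data frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based base-pair position), \code{minor}, \code{major}.
#'   Positions must be strictly increasing within each chromosome.
#' @param subject_ids character vector of subject identifiers; defaults to
#'   \code{"S1"..."Sn"}.
#' @param missing_mask optional logical matrix marking entries that were
#'   missing in the source data (before imputation).
#'
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{dosages}, \code{snp_meta}, \code{subject_ids}, \code{missing_mask}
#'   and \code{snp_variance} (per-SNP sample variance, \code{NA} while
#'   missing entries remain).
#' @seealso [impute_missing_mean()], [orient_minor_allele()],
#'   [read_mean_genotype()], [simulate_genotypes()]
#' @export
genotype_matrix <- function(dosages, snp_meta, subject_ids = NULL,
                            missing_mask = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.data.frame(snp_meta))
    stop_input("snp_meta must be a data frame")
  need <- c("snp_id", "chrom", "pos", "minor", "major")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss))
    stop_input("snp_meta lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(snp_meta) != ncol(dosages))
    stop_input("snp_meta has %d rows but dosage matrix has %d columns",
               nrow(snp_meta), ncol(dosages))
  snp_meta$snp_id <- as.character(snp_meta$snp_id)
  snp_meta$chrom  <- as.character(snp_meta$chrom)
  snp_meta$pos    <- as.numeric(snp_meta$pos)
  rownames(snp_meta) <- NULL

  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(dosages))
    stop_input("dosage %g at subject %d, SNP '%s' outside [0, 2]",
               dosages[bad[1L]], ij[1L], snp_meta$snp_id[ij[2L]])
  }
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (any(diff(p) <= 0))
      stop_input("positions not strictly increasing on chromosome %s", ch)
  }
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(nrow(dosages)))
  if (length(subject_ids) != nrow(dosages))
    stop_input("subject_ids length %d != %d subjects",
               length(subject_ids), nrow(dosages))
  if (!is.null(missing_mask)) {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(dosages)))
      stop_input("missing_mask dimensions differ from dosages")
    storage.mode(missing_mask) <- "logical"
  }

  obj <- structure(list(
    dosages      = dosages,
    snp_meta     = snp_meta,
    subject_ids  = as.character(subject_ids),
    missing_mask = missing_mask,
    snp_variance = rep(NA_real_, ncol(dosages))
  ), class = "genotype_matrix")
  if (!anyNA(dosages))
    obj$snp_variance <- apply(dosages, 2L, stats::var)
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_meta$chrom))))
  nmiss <- if (is.null(x$missing_mask)) sum(is.na(x$dosages))
           else sum(x$missing_mask)
  cat(sprintf("  missing entries: %d; imputed: %s\n", nmiss,
              if (anyNA(x$dosages)) "no" else "yes"))
  invisible(x)
}

#' Number of subjects / SNPs in a genotype matrix
#' @param G a [genotype_matrix()].
#' @return integer count.
#' @export
n_subjects <- function(G) nrow(G$dosages)

#' @rdname n_subjects
#' @export
n_snps <- function(G) ncol(G$dosages)

#' Subset a genotype matrix
#'
#' Column (SNP) or row (subject) subsetting that keeps dosages, metadata,
#' mask and variances aligned.  SNP order must be preserved so that positions
#' remain sorted.
#'
#' @param G a [genotype_matrix()].
#' @param idx integer or logical index vector.
#' @return a [genotype_matrix()].
#' @export
subset_snps <- function(G, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L) stop_input("SNP subset is empty")
  out <- genotype_matrix(G$dosages[, idx, drop = FALSE],
                         G$snp_meta[idx, , drop = FALSE],
                         G$subject_ids,
                         if (!is.null(G$missing_mask))
                           G$missing_mask[, idx, drop = FALSE])
  out$snp_variance <- G$snp_variance[idx]
  out
}

#' @rdname subset_snps
#' @export
subset_subjects <- function(G, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L) stop_input("subject subset is empty")
  out <- genotype_matrix(G$dosages[idx, , drop = FALSE],
                         G$snp_meta,
                         G$subject_ids[idx],
                         if (!is.null(G$missing_mask))
                           G$missing_mask[idx, , drop = FALSE])
  out
}

#' Binary phenotype vector
#'
#' Validates a vector of 0/1 case-control labels aligned to the subjects of a
#' genotype matrix.  At least one case and one control are required.
#'
#' @param labels numeric or integer vector of 0 (control) / 1 (case).
#' @return an integer vector of class \code{"phenotype_vector"}.
#' @export
phenotype_vector <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop_input("phenotype contains NA; drop those subjects first")
  if (!all(labels %in% c(0L, 1L)))
    stop_input("phenotype labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop_input("phenotype is constant: need at least one case and one control")
  structure(labels, class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("<phenotype_vector> %d subjects: %d cases, %d controls\n",
              length(x), sum(x == 1L), sum(x == 0L)))
  invisible(x)
}
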