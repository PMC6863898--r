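# Readers/writers for the mean-genotype (BIMBAM-style) and PLINK text
# dialects, plus the two preprocessing steps applied to every dataset:
# minor-allele orientation and per-SNP mean imputation of missing genotypes.

#' Read a mean-genotype dataset (BIMBAM-style text files)
#'
#' The genotype file carries one SNP per row:
#' \code{snp_id, allele1, allele0, dosage_1 ... dosage_n}, comma or
#' whitespace separated, dosages in \code{[0, 2]} with \code{NA} for missing.
#' The position file carries \code{snp_id, bp, chrom} and the phenotype file
#' one 0/1 (or \code{NA}) label per line.  Subjects with a missing phenotype
#' are dropped (from both files) with a warning stating the count.
#'
#' @param genotype_path,position_path,phenotype_path file paths.
#' @return list with components \code{genotypes} (a [genotype_matrix()],
#'   SNPs sorted by chromosome and position) and \code{phenotype}
#'   (a [phenotype_vector()]).
#' @export
read_mean_genotype <- function(genotype_path, position_path, phenotype_path) {
  for (p in c(genotype_path, position_path, phenotype_path))
    if (!file.exists(p)) stop_input("file not found: %s", p)

  rows <- readLines(genotype_path)
  rows <- rows[nzchar(trimws(rows))]
  if (!length(rows)) stop_input("empty genotype file: %s", genotype_path)
  toks <- strsplit(rows, "[,[:space:]]+")
  nf <- lengths(toks)
  if (length(unique(nf)) != 1L)
    stop_input("genotype file rows have inconsistent field counts (row %d)",
               which(nf != nf[1L])[1L])
  n_subj <- nf[1L] - 3L
  if (n_subj < 1L) stop_input("genotype file has no dosage columns")
  snp_id <- vapply(toks, `[[`, "", 1L)
  a1 <- vapply(toks, `[[`, "", 2L)
  a0 <- vapply(toks, `[[`, "", 3L)
  dos <- matrix(NA_real_, nrow = n_subj, ncol = length(toks))
  for (j in seq_along(toks)) {
    v <- toks[[j]][-(1:3)]
    v[v %in% c("NA", "na", "?")] <- NA
    x <- suppressWarnings(as.numeric(v))
    if (any(is.na(x) & !is.na(v)))
      stop_input("non-numeric dosage in genotype row %d (SNP %s)", j, snp_id[j])
    bad <- which(!is.na(x) & (x < 0 | x > 2))
    if (length(bad))
      stop_input("dosage %g outside [0, 2] in genotype row %d (SNP %s), subject column %d",
                 x[bad[1L]], j, snp_id[j], bad[1L])
    dos[, j] <- x
  }

  posdf <- utils::read.table(position_path, header = FALSE,
                             col.names = c("snp_id", "bp", "chrom"),
                             colClasses = c("character", "numeric", "character"),
                             sep = "", fill = FALSE)
  unknown <- setdiff(snp_id, posdf$snp_id)
  if (length(unknown))
    stop_input("SNP(s) absent from position file: %s",
               paste(utils::head(unknown, 5L), collapse = ", "))
  m <- match(snp_id, posdf$snp_id)
  meta <- data.frame(snp_id = snp_id, chrom = posdf$chrom[m],
                     pos = posdf$bp[m], minor = a1, major = a0,
                     stringsAsFactors = FALSE)

  ph_raw <- readLines(phenotype_path)
  ph_raw <- trimws(ph_raw[nzchar(trimws(ph_raw))])
  if (length(ph_raw) != n_subj)
    stop_input("phenotype file has %d entries but genotype file has %d subjects",
               length(ph_raw), n_subj)
  ph <- suppressWarnings(as.numeric(ifelse(ph_raw %in% c("NA", "na"), NA, ph_raw)))
  keep <- !is.na(ph)
  if (any(!keep)) {
    warning(sprintf("dropping %d subject(s) with missing phenotype", sum(!keep)))
    dos <- dos[keep, , drop = FALSE]
    ph <- ph[keep]
  }
  if (any(!ph %in% c(0, 1)))
    stop_input("phenotype values must be 0/1 (got %s)",
               paste(utils::head(setdiff(ph, c(0, 1)), 3L), collapse = ", "))

  ord <- order(meta$chrom, meta$pos)
  meta <- meta[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  G <- genotype_matrix(dos, meta, missing_mask = is.na(dos))
  list(genotypes = G, phenotype = phenotype_vector(ph))
}

#' Write a mean-genotype dataset
#'
#' Inverse of [read_mean_genotype()]: writes the three text files in the same
#' dialect.  Missing dosages are written as \code{NA}.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype_vector()] (or NULL to skip the phenotype file).
#' @param genotype_path,position_path,phenotype_path output paths.
#' @return invisibly, the three paths.
#' @export
write_mean_genotype <- function(G, y, genotype_path, position_path,
                                phenotype_path = NULL) {
  meta <- G$snp_meta
  lines <- vapply(seq_len(n_snps(G)), function(j) {
    paste(c(meta$snp_id[j], meta$minor[j], meta$major[j],
            vapply(G$dosages[, j], function(d)
              if (is.na(d)) "NA" else sprintf("%.17g", d),
              "")),
          collapse = ", ")
  }, "")
  writeLines(lines, genotype_path)
  utils::write.table(data.frame(meta$snp_id, format(meta$pos, scientific = FALSE, trim = TRUE),
                                meta$chrom),
                     position_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(y) && !is.null(phenotype_path))
    writeLines(as.character(as.integer(y)), phenotype_path)
  invisible(c(genotype_path, position_path, phenotype_path))
}

#' Read PLINK text pedigree files (.ped / .map)
#'
#' Converts allele pairs to minor-allele dosages and the PLINK 1/2 phenotype
#' coding to 0/1 (2 = case).  A "0" allele denotes a missing call; a subject
#' missing either allele at a SNP gets a missing dosage there.  Triallelic
#' SNPs are rejected.
#'
#' @param ped_path,map_path file paths.
#' @return list with \code{genotypes} and \code{phenotype} as in
#'   [read_mean_genotype()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop_input("file not found: %s", p)
  mapdf <- utils::read.table(map_path, header = FALSE,
                             col.names = c("chrom", "snp_id", "cm", "bp"),
                             colClasses = c("character", "character",
                                            "numeric", "numeric"))
  p <- nrow(mapdf)
  rows <- readLines(ped_path)
  rows <- rows[nzchar(trimws(rows))]
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != 6L + 2L * p)) {
    bad <- which(nf != 6L + 2L * p)[1L]
    if ((nf[bad] - 6L) %% 2L == 1L)
      stop_input("odd allele count in .ped row %d", bad)
    stop_input(".ped row %d has %d fields, expected %d for %d SNPs",
               bad, nf[bad], 6L + 2L * p, p)
  }
  n <- length(toks)
  ids <- vapply(toks, `[[`, "", 2L)
  ph_code <- vapply(toks, `[[`, "", 6L)
  if (!all(ph_code %in% c("1", "2")))
    stop_input("unsupported .ped phenotype code(s): %s",
               paste(unique(setdiff(ph_code, c("1", "2"))), collapse = ", "))
  y <- as.integer(ph_code == "2")

  al <- matrix("", nrow = n, ncol = 2L * p)
  for (i in seq_len(n)) al[i, ] <- toks[[i]][-(1:6)]
  a1 <- al[, seq(1L, 2L * p, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * p, by = 2L), drop = FALSE]

  dos <- matrix(NA_real_, nrow = n, ncol = p)
  minor <- major <- character(p)
  for (j in seq_len(p)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L)
      stop_input("SNP %s is not biallelic (alleles: %s)",
                 mapdf$snp_id[j], paste(alleles, collapse = ","))
    if (length(alleles) == 0L)
      stop_input("SNP %s has no observed alleles", mapdf$snp_id[j])
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    counts <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    mi <- if (counts[1L] <= counts[2L]) 1L else 2L
    minor[j] <- alleles[mi]; major[j] <- alleles[-mi][1L]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    dos[ok, j] <- (a1[ok, j] == minor[j]) + (a2[ok, j] == minor[j])
  }
  meta <- data.frame(snp_id = mapdf$snp_id, chrom = mapdf$chrom,
                     pos = mapdf$bp, minor = minor, major = major,
                     stringsAsFactors = FALSE)
  ord <- order(meta$chrom, meta$pos)
  G <- genotype_matrix(dos[, ord, drop = FALSE], meta[ord, , drop = FALSE],
                       subject_ids = ids, missing_mask = is.na(dos[, ord, drop = FALSE]))
  list(genotypes = G, phenotype = phenotype_vector(y))
}

#' Impute missing genotypes by the per-SNP sample mean
#'
#' Every missing dosage is replaced by the mean of the observed dosages of
#' its SNP; observed entries are unchanged.  Per-SNP sample variances are
#' (re)computed after imputation, since they parameterise the effect-size
#' prior of the sampler.
#'
#' @param G a [genotype_matrix()], each SNP having at least one observed value.
#' @return a [genotype_matrix()] with no missing entries and filled
#'   \code{snp_variance}.
#' @export
impute_missing_mean <- function(G) {
  dos <- G$dosages
  mask <- if (!is.null(G$missing_mask)) G$missing_mask | is.na(dos) else is.na(dos)
  if (any(mask)) {
    full <- which(colSums(!mask) == 0L)
    if (length(full))
      stop_input("SNP(s) with no observed genotype: %s",
                 paste(utils::head(G$snp_meta$snp_id[full], 5L), collapse = ", "))
    dos[mask] <- NA_real_
    cm <- colMeans(dos, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    dos[idx] <- cm[idx[, 2L]]
  }
  out <- genotype_matrix(dos, G$snp_meta, G$subject_ids, mask)
  out$snp_variance <- apply(dos, 2L, stats::var)
  out
}

#' Orient every SNP to minor-allele dosage coding
#'
#' Any SNP whose dosage-implied allele frequency exceeds 0.5 is flipped
#' (\code{x -> 2 - x}) and its allele labels swapped, so that dosages count
#' copies of the minor allele.  A frequency of exactly 0.5 keeps the input
#' orientation; the operation is idempotent.
#'
#' @param G a [genotype_matrix()] (missing entries allowed; they are ignored
#'   when computing frequencies and stay missing).
#' @return a [genotype_matrix()] with all allele frequencies \eqn{\le} 0.5.
#' @export
orient_minor_allele <- function(G) {
  dos <- G$dosages
  freq <- colMeans(dos, na.rm = TRUE) / 2
  flip <- which(freq > 0.5)
  meta <- G$snp_meta
  if (length(flip)) {
    dos[, flip] <- 2 - dos[, flip]
    tmp <- meta$minor[flip]
    meta$minor[flip] <- meta$major[flip]
    meta$major[flip] <- tmp
  }
  out <- genotype_matrix(dos, meta, G$subject_ids, G$missing_mask)
  if (!anyNA(dos)) out$snp_variance <- apply(dos, 2L, stats::var)
  out
}
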