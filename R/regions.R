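# Sliding-window partition of each chromosome's ordered SNPs into
# overlapping fixed-size regions.

#' Partition one chromosome's SNPs into overlapping windows
#'
#' Windows of \code{window} SNPs start at offsets 0, \code{step},
#' \code{2*step}, ...  A chromosome shorter than \code{window} yields a
#' single window of all its SNPs; otherwise, whenever the last stepped
#' window would not reach the chromosome end, a final window anchored to the
#' last \code{window} SNPs is appended, so that every full-chromosome window
#' has equal size and every SNP is covered.  With the default
#' \code{step = window/2}, every SNP further than \code{window/2} from a
#' chromosome end belongs to exactly two windows.
#'
#' @param n_snps_on_chrom number of SNPs on the chromosome (>= 1).
#' @param window window size in SNPs (>= 2; default 1000).
#' @param step offset between window starts (default \code{window/2},
#'   i.e. an overlap of half a window).
#' @return integer matrix with one row per window and columns
#'   \code{start}, \code{end} (1-based, inclusive SNP indices).
#' @export
partition_chromosome <- function(n_snps_on_chrom, window = 1000L,
                                 step = window %/% 2L) {
  n <- as.integer(n_snps_on_chrom)
  window <- as.integer(window); step <- as.integer(step)
  if (n < 1L) stop_input("chromosome has no SNPs")
  if (window < 2L) stop_input("window must be >= 2")
  if (step < 1L || step > window)
    stop_input("step must be in [1, window]")
  if (n <= window)
    return(cbind(start = 1L, end = n))
  starts <- seq.int(1L, n - window + 1L, by = step)
  if (starts[length(starts)] + window - 1L < n)
    starts <- c(starts, n - window + 1L)
  cbind(start = starts, end = starts + window - 1L)
}

#' Partition a genome's SNPs into overlapping windows
#'
#' Applies [partition_chromosome()] separately to each chromosome of a
#' genotype matrix (regions are numbered from 1 within each chromosome) and
#' records the base-pair positions of the first and last SNP included in
#' every region.
#'
#' @param G a [genotype_matrix()] whose SNP metadata is sorted by
#'   (chromosome, position).
#' @param window,step as in [partition_chromosome()].
#' @return data frame of class \code{"region_index"} with columns
#'   \code{chrom}, \code{rank_on_chrom}, \code{snp_start}, \code{snp_end}
#'   (global 1-based column indices into \code{G}, inclusive),
#'   \code{n_snps}, \code{start_pos}, \code{end_pos}.
#' @export
partition_genome <- function(G, window = 1000L, step = window %/% 2L) {
  meta <- G$snp_meta
  if (nrow(meta) == 0L) stop_input("no SNPs to partition")
  chroms <- unique(meta$chrom)
  if (is.unsorted(match(meta$chrom, chroms)) ||
      any(unlist(lapply(chroms, function(ch)
        diff(meta$pos[meta$chrom == ch]) <= 0))))
    stop_input("SNP metadata must be sorted by (chrom, pos)")

  out <- list()
  for (ch in chroms) {
    idx <- which(meta$chrom == ch)
    spans <- partition_chromosome(length(idx), window, step)
    gs <- idx[spans[, "start"]]
    ge <- idx[spans[, "end"]]
    out[[ch]] <- data.frame(
      chrom = ch,
      rank_on_chrom = seq_len(nrow(spans)),
      snp_start = gs, snp_end = ge,
      n_snps = ge - gs + 1L,
      start_pos = meta$pos[gs], end_pos = meta$pos[ge],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("region_index", "data.frame")
  attr(res, "window") <- as.integer(window)
  attr(res, "step") <- as.integer(step)
  res
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("<region_index> %d region(s) on %d chromosome(s) (window %d, step %d)\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "window") %||% NA_integer_,
              attr(x, "step") %||% NA_integer_))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Write a regions table
#' @param regions a [partition_genome()] result.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(
    data.frame(chrom = regions$chrom, rank = regions$rank_on_chrom,
               n_snps = regions$n_snps, start_pos = regions$start_pos,
               end_pos = regions$end_pos),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
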