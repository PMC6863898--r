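# End-to-end orchestration: (simulate |  read) -> preprocess -> partition ->
# discovery scan with permutation significance -> validation -> consensus,
# with every artefact written as TSV and every seed recorded, so a rerun of
# the same configuration reproduces all numeric outputs bit-identically.

#' Assemble and validate a pipeline configuration
#'
#' @param discovery either \code{list(files = list(genotype, position,
#'   phenotype))} pointing at mean-genotype text files, or
#'   \code{list(simulate = list(...))} with arguments for
#'   [simulate_genotypes()] / [simulate_phenotype()] (\code{n_subjects},
#'   \code{layout}, \code{n_causal}, \code{per_variant_h}, \code{prevalence},
#'   \code{balanced}, optional \code{causal_indices}, \code{missing_rate}).
#' @param validation like \code{discovery}, or NULL to skip validation; a
#'   simulated validation block may add \code{keep_fraction} to subset the
#'   panel to an overlapping genotyping platform.
#' @param window,step sliding-window parameters (see [partition_genome()]).
#'   1000/500 at full scale.
#' @param priors a [bvs_priors()].
#' @param mcmc a [bvs_config()] (its seed is overridden by derived seeds).
#' @param discovery_alpha,discovery_B family-wise alpha and permutation
#'   budget of the discovery scan (full-scale defaults 0.1 and 100000).
#' @param validation_alpha,validation_B same for validation (0.05, 1000).
#' @param batch permutations between early-stop checks.
#' @param consensus list of [overlap_consensus()] settings
#'   (\code{top_region_frac}, \code{top_snp_frac}, \code{window_bp},
#'   \code{r2_threshold}).
#' @param master_seed integer; every stage seed derives from it.
#' @param out_dir output directory (created if needed).
#' @return validated \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(discovery, validation = NULL,
                            window = 1000L, step = window %/% 2L,
                            priors = bvs_priors(), mcmc = bvs_config(),
                            discovery_alpha = 0.1, discovery_B = 100000L,
                            validation_alpha = 0.05, validation_B = 1000L,
                            batch = 100L,
                            consensus = list(), master_seed = 1L,
                            out_dir = tempfile("regionbvs_run_")) {
  for (a in c(discovery_alpha, validation_alpha))
    if (a <= 0 || a >= 1) stop_input("alpha values must be in (0, 1), got %g", a)
  if (discovery_B < 1L || validation_B < 1L) stop_input("permutation budgets must be >= 1")
  if (!inherits(priors, "bvs_priors")) stop_input("priors must come from bvs_priors()")
  if (!inherits(mcmc, "bvs_config")) stop_input("mcmc must come from bvs_config()")
  if (!is.list(discovery) || is.null(discovery$files) == is.null(discovery$simulate))
    stop_input("discovery must name exactly one of 'files' or 'simulate'")
  cons <- utils::modifyList(
    list(top_region_frac = 0.05, top_snp_frac = 0.01,
         window_bp = 100000, r2_threshold = 0.2), consensus)
  structure(list(discovery = discovery, validation = validation,
                 window = as.integer(window), step = as.integer(step),
                 priors = priors, mcmc = mcmc,
                 discovery_alpha = discovery_alpha,
                 discovery_B = as.integer(discovery_B),
                 validation_alpha = validation_alpha,
                 validation_B = as.integer(validation_B),
                 batch = as.integer(batch), consensus = cons,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Materialise one dataset block (discovery or validation) of the config.
load_dataset <- function(block, seed, log) {
  if (!is.null(block$files)) {
    f <- block$files
    ds <- read_mean_genotype(f$genotype, f$position, f$phenotype)
    log("read mean-genotype files: ", f$genotype)
    G <- orient_minor_allele(impute_missing_mean(ds$genotypes))
    return(list(G = G, y = ds$phenotype))
  }
  s <- block$simulate
  gseed <- derive_seed(seed, 1L); pseed <- derive_seed(seed, 2L)
  log(sprintf("simulating genotypes (seed %d) and phenotype (seed %d)", gseed, pseed))
  G <- simulate_genotypes(s$n_subjects, s$layout,
                          bp_start = s$bp_start %||% 100000L,
                          bp_step = s$bp_step %||% 5000L, seed = gseed)
  if (!is.null(s$keep_fraction) && s$keep_fraction < 1)
    G <- make_platform_subset(G, s$keep_fraction, seed = derive_seed(seed, 4L))
  sim <- simulate_phenotype(G, n_causal = s$n_causal %||% 0L,
                            per_variant_h = s$per_variant_h %||% 0.0017,
                            prevalence = s$prevalence %||% 0.01,
                            balanced = isTRUE(s$balanced), seed = pseed,
                            causal_indices = s$causal_indices)
  G <- subset_subjects(G, sim$subjects)
  if (!is.null(s$missing_rate) && s$missing_rate > 0) {
    G <- impute_missing_mean(inject_missing(G, s$missing_rate,
                                            seed = derive_seed(seed, 3L)))
    G <- orient_minor_allele(G)
  }
  list(G = G, y = sim$phenotype, truth = sim$truth)
}

#' Run the full discovery-validation-consensus pipeline
#'
#' Executes every stage of the configured workflow and writes, under
#' \code{config$out_dir}: \code{regions.tsv}; \code{discovery_scan.tsv}
#' (one row per region with Chr, Region, start/end position, rank and the
#' discovery empirical p) and \code{discovery_pips.tsv} (per-SNP PIPs with
#' the \code{-log10(1 - PIP)} Manhattan column); \code{region_sums.tsv};
#' \code{validation.tsv} and \code{consensus_pairs.tsv} /
#' \code{consensus_summary.tsv} when a validation dataset is configured;
#' Manhattan and region-sum plots as PNG; and \code{run_log.txt} recording
#' every parameter and derived seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with \code{scan}, \code{regions},
#'   \code{validation}, \code{consensus}, \code{truth} (for simulated data)
#'   and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  log <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  log(sprintf("master_seed: %d", config$master_seed))
  log(sprintf("window: %d  step: %d", config$window, config$step))
  log(sprintf("priors: h in [%g, %g], target size %g-%g, cap %d",
              config$priors$h_min, config$priors$h_max,
              config$priors$target_size_min, config$priors$target_size_max,
              config$priors$max_model_size))
  log(sprintf("mcmc: %d iterations, burn-in %g, thin %d, %d chain(s), %s trait",
              config$mcmc$n_iter, config$mcmc$burn_in, config$mcmc$thin,
              config$mcmc$n_chains, config$mcmc$trait_mode))

  disc_seed <- derive_seed(config$master_seed, 101L)
  disc <- stage("discovery data", load_dataset(config$discovery, disc_seed, log))
  log(sprintf("discovery: %d subjects (%d cases), %d SNPs",
              n_subjects(disc$G), sum(disc$y == 1L), n_snps(disc$G)))

  regions <- stage("partition", partition_genome(disc$G, config$window, config$step))
  per_chrom <- table(regions$chrom)
  log(sprintf("regions: %d total (%s)", nrow(regions),
              paste(sprintf("chr%s: %d", names(per_chrom), as.integer(per_chrom)),
                    collapse = ", ")))
  write_regions(regions, file.path(config$out_dir, "regions.tsv"))

  scan_seed <- derive_seed(config$master_seed, 102L)
  log(sprintf("discovery scan master seed: %d; alpha = %g over %d regions; B_target = %d",
              scan_seed, config$discovery_alpha, nrow(regions), config$discovery_B))
  scan <- stage("discovery scan",
                genomewide_scan(disc$G, regions, disc$y, config$priors,
                                config$mcmc, alpha = config$discovery_alpha,
                                B_target = config$discovery_B,
                                batch = config$batch, master_seed = scan_seed))
  for (i in seq_len(nrow(scan)))
    log(sprintf("region %s/%d: sum_pip %.4f, p %s, B_done %d%s",
                scan$chrom[i], scan$rank_on_chrom[i], scan$sum_pip[i],
                scan$p_text[i], scan$B_done[i],
                if (scan$stopped_early[i]) " (early stop: threshold unreachable)" else ""))

  scan_tab <- data.frame(
    Chr = scan$chrom, Region = scan$rank_on_chrom,
    Start_position = scan$start_pos, End_position = scan$end_pos,
    Rank = scan$rank, P_disc = scan$p_text,
    sum_pip = scan$sum_pip, r = scan$r, B_done = scan$B_done,
    stopped_early = scan$stopped_early, significant = scan$significant)
  pip_tab <- do.call(rbind, attr(scan, "pip_tables"))
  write_tsv <- function(d, f) {
    utils::write.table(d, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(pip_tab, "discovery_pips.tsv")
  write_tsv(data.frame(chrom = scan$chrom, rank = scan$rank_on_chrom,
                       sum_pip = scan$sum_pip, mean_pip = scan$mean_pip),
            "region_sums.tsv")

  grDevices::png(file.path(config$out_dir, "manhattan_discovery.png"),
                 width = 1200, height = 400)
  render_manhattan(pip_tab, main = "Discovery: per-SNP PIP")
  grDevices::dev.off()
  grDevices::png(file.path(config$out_dir, "region_sums_discovery.png"),
                 width = 1200, height = 400)
  render_region_sums(scan, main = "Discovery: per-region sum of PIPs")
  grDevices::dev.off()

  validation <- NULL; consensus <- NULL; val <- NULL
  if (!is.null(config$validation)) {
    val_seed <- derive_seed(config$master_seed, 103L)
    val <- stage("validation data", load_dataset(config$validation, val_seed, log))
    log(sprintf("validation: %d subjects (%d cases), %d SNPs",
                n_subjects(val$G), sum(val$y == 1L), n_snps(val$G)))
    cand <- scan[scan$significant, , drop = FALSE]
    if (!nrow(cand)) {
      log("no significant discovery regions; validating the top-ranked region")
      cand <- scan[1L, , drop = FALSE]
    }
    vseed <- derive_seed(config$master_seed, 104L)
    log(sprintf("validation master seed: %d; alpha = %g over %d candidate(s); B = %d",
                vseed, config$validation_alpha, nrow(cand), config$validation_B))
    validation <- stage("validation",
                        validate_regions(cand, val$G, val$y, config$priors,
                                         config$mcmc, B = config$validation_B,
                                         alpha = config$validation_alpha,
                                         master_seed = vseed))
    write_tsv(validation, "validation.tsv")

    # consensus: an independent scan of the validation data, no permutations
    cseed <- derive_seed(config$master_seed, 105L)
    regions_val <- partition_genome(val$G, config$window, config$step)
    scan_val <- stage("validation scan",
                      genomewide_scan(val$G, regions_val, val$y, config$priors,
                                      config$mcmc, alpha = config$discovery_alpha,
                                      B_target = 1L, batch = 1L,
                                      master_seed = cseed))
    cons <- config$consensus
    consensus <- stage("consensus",
                       overlap_consensus(scan, scan_val, disc$G,
                                         top_region_frac = cons$top_region_frac,
                                         top_snp_frac = cons$top_snp_frac,
                                         window_bp = cons$window_bp,
                                         r2_threshold = cons$r2_threshold))
    write_tsv(consensus$pairs, "consensus_pairs.tsv")
    write_tsv(consensus$summary, "consensus_summary.tsv")
    log(sprintf("consensus: %d pair(s), %.1f%% in LD at r2 >= %g",
                consensus$summary$n_pairs,
                consensus$summary$pct_in_ld %||% NA_real_,
                cons$r2_threshold))

    m <- match(paste(validation$chrom, validation$rank_on_chrom),
               paste(scan_tab$Chr, scan_tab$Region))
    scan_tab$P_vali <- NA_character_
    scan_tab$P_vali[m] <- validation$p_text
  }
  write_tsv(scan_tab, "discovery_scan.tsv")
  writeLines(log_lines, log_path)

  invisible(list(scan = scan, regions = regions, validation = validation,
                 consensus = consensus, truth = disc$truth,
                 truth_validation = val$truth,
                 out_dir = config$out_dir))
}

# Shared Manhattan-style panel: genome-ordered x axis with cumulative
# offsets and alternating chromosome shading.
manhattan_panel <- function(df, ylab = expression(-log[10](1 - PIP)), ...) {
  chroms <- unique(df$chrom)
  offs <- 0; xs <- numeric(nrow(df)); centers <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    sel <- df$chrom == chroms[i]
    xs[sel] <- offs + df$pos[sel] - min(df$pos[sel])
    centers[i] <- mean(range(xs[sel]))
    offs <- max(xs[sel]) + 1
  }
  cols <- rep(c("grey30", "steelblue"), length.out = length(chroms))
  graphics::plot(xs, df$y, pch = 16, cex = 0.5,
                 col = cols[match(df$chrom, chroms)],
                 xaxt = "n", xlab = "chromosome", ylab = ylab, ...)
  graphics::axis(1, at = centers, labels = chroms)
  invisible(xs)
}

#' Manhattan plot of per-SNP posterior inclusion probabilities
#'
#' Genome-ordered scatter of \code{-log10(1 - PIP)} (PIPs clipped at
#' \code{1 - 1e-6}) with alternating chromosome colours.
#'
#' @param per_snp data frame with columns \code{chrom}, \code{pos},
#'   \code{pip} (e.g. the \code{discovery_pips.tsv} table or a scan's
#'   \code{pip_tables} attribute, row-bound).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the y values plotted.
#' @export
render_manhattan <- function(per_snp, ...) {
  df <- data.frame(chrom = as.character(per_snp$chrom), pos = per_snp$pos,
                   y = -log10(pmax(1 - per_snp$pip, 1e-6)))
  manhattan_panel(df, ...)
  invisible(df$y)
}

#' Per-region sum-of-PIPs plot
#'
#' @param scan a [genomewide_scan()] result (or any data frame with
#'   \code{chrom}, \code{rank_on_chrom}, \code{sum_pip}).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted values.
#' @export
render_region_sums <- function(scan, ...) {
  df <- as.data.frame(scan)
  df <- df[order(df$chrom, df$rank_on_chrom), ]
  df$pos <- df$rank_on_chrom
  df$y <- df$sum_pip
  manhattan_panel(df, ylab = "sum of PIPs", ...)
  invisible(df$y)
}
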