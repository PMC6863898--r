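test_that("interval mapping is inclusive, monotone, and warns when empty", {
  vmeta <- data.frame(snp_id = paste0("v", 1:5), chrom = "3",
                      pos = c(50, 100, 150, 200, 250),
                      minor = "A", major = "G")
  region <- list(chrom = "3", start_pos = 100, end_pos = 200)
  expect_equal(map_region_to_validation(region, vmeta), 2:4)
  # identical panel maps to itself
  region_all <- list(chrom = "3", start_pos = 50, end_pos = 250)
  expect_equal(map_region_to_validation(region_all, vmeta), 1:5)
  # monotone: enlarging the interval never removes SNPs
  wider <- map_region_to_validation(list(chrom = "3", start_pos = 90,
                                         end_pos = 210), vmeta)
  expect_true(all(2:4 %in% wider))
  expect_warning(map_region_to_validation(
    list(chrom = "7", start_pos = 1, end_pos = 10), vmeta), "absent")
  expect_warning(map_region_to_validation(
    list(chrom = "3", start_pos = 101, end_pos = 102), vmeta), "no validation SNPs")
})

test_that("a half-density platform maps about half the SNPs of a region", {
  G <- simulate_genotypes(50, list("1" = list(
    block_spec(1000, rho = 0, maf_range = c(0.1, 0.5)))), seed = 3)
  S <- make_platform_subset(G, 0.5, seed = 4)
  region <- list(chrom = "1", start_pos = G$snp_meta$pos[1],
                 end_pos = G$snp_meta$pos[1000])
  idx <- map_region_to_validation(region, S$snp_meta)
  expect_equal(length(idx), 500)      # exact here: the subset spans the region
})

test_that("ld_r2 follows the Pearson formula and its symmetries", {
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(2, 1, 0, 2, 1, 0)), 1)
  a <- c(0, 1, 2, 1, 0, 2, 1, 0)
  b <- c(0, 1, 1, 1, 0, 2, 0, 0)
  # independent oracle: explicit Pearson formula
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ld_r2(a, b), r^2, tolerance = 1e-12)
  expect_equal(ld_r2(b, a), ld_r2(a, b))
  expect_equal(ld_r2(2 - a, b), ld_r2(a, b))
  expect_error(ld_r2(a, b[1:5]), "length")
  expect_error(ld_r2(rep(1, 8), b), "constant")
  expect_error(ld_r2(a[1:2], b[1:2]), "3 subjects")
})

# A small two-platform scenario with one strongly causal block shared by
# both datasets, used by the consensus tests below.
consensus_fixture <- function() {
  lay <- list("1" = list(block_spec(20, rho = 0.9, maf_range = c(0.2, 0.4)),
                         block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))),
              "2" = list(block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))))
  G <- simulate_genotypes(400, lay, bp_step = 2000, seed = 11)
  sim <- simulate_phenotype(G, n_causal = 2, per_variant_h = 0.15,
                            prevalence = 0.5, seed = 12,
                            causal_indices = c(5L, 10L))   # inside the LD block
  priors <- bvs_priors(h_max = 0.5)
  cfg <- bvs_config(n_iter = 1500, seed = 13)
  regions <- partition_genome(G, window = 20)
  scan <- genomewide_scan(G, regions, sim$phenotype, priors, cfg,
                          alpha = 0.1, B_target = 5, batch = 5, master_seed = 14)
  list(G = G, y = sim$phenotype, priors = priors, cfg = cfg,
       regions = regions, scan = scan)
}

test_that("self-comparison yields 100% consensus at distance 0", {
  fx <- consensus_fixture()
  res <- overlap_consensus(fx$scan, fx$scan, fx$G,
                           top_region_frac = 0.35, top_snp_frac = 0.1,
                           window_bp = 0, r2_threshold = 0.2)
  expect_gt(res$summary$n_pairs, 0)
  expect_true(all(res$pairs$snp_a == res$pairs$snp_b))
  expect_true(all(res$pairs$distance_bp == 0))
  expect_true(all(res$pairs$r2 == 1))
  expect_equal(res$summary$pct_in_ld, 100)
})

test_that("disjoint chromosomes produce an empty overlap set", {
  fx <- consensus_fixture()
  scan_b <- fx$scan
  scan_b$chrom <- paste0("X", scan_b$chrom)
  pt <- attr(scan_b, "pip_tables")
  for (i in seq_along(pt)) pt[[i]]$chrom <- paste0("X", pt[[i]]$chrom)
  attr(scan_b, "pip_tables") <- pt
  res <- overlap_consensus(fx$scan, scan_b, fx$G,
                           top_region_frac = 0.35, top_snp_frac = 0.1)
  expect_equal(res$summary$n_pairs, 0L)
  expect_true(is.na(res$summary$pct_in_ld))
})

test_that("two platforms sharing a causal LD block meet in the consensus set", {
  fx <- consensus_fixture()
  # second platform: independent cohort on a thinned panel, same layout
  lay <- list("1" = list(block_spec(20, rho = 0.9, maf_range = c(0.2, 0.4)),
                         block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))),
              "2" = list(block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))))
  G2full <- simulate_genotypes(400, lay, bp_step = 2000, seed = 21)
  sim2 <- simulate_phenotype(G2full, n_causal = 2, per_variant_h = 0.15,
                             prevalence = 0.5, seed = 22,
                             causal_indices = c(5L, 10L))
  G2 <- make_platform_subset(G2full, 0.6, seed = 23)
  reg2 <- partition_genome(G2, window = 20)
  scan2 <- genomewide_scan(G2, reg2, sim2$phenotype, fx$priors, fx$cfg,
                           alpha = 0.1, B_target = 5, batch = 5, master_seed = 24)
  res <- overlap_consensus(fx$scan, scan2, fx$G,
                           top_region_frac = 0.35, top_snp_frac = 0.1,
                           window_bp = 100000, r2_threshold = 0.2)
  expect_gt(res$summary$n_pairs, 0)
  # pairs from the shared causal block are in LD
  blockA <- paste0("chr1_s", 1:20)
  block_pairs <- res$pairs$snp_a %in% blockA & res$pairs$snp_b %in% blockA
  expect_true(any(block_pairs))
  expect_true(any(res$pairs$in_ld[block_pairs]))
  expect_true(all(res$pairs$in_ld == (!is.na(res$pairs$r2) &
                                      res$pairs$r2 >= 0.2)))
  # order invariance of the consensus percentage
  res_rev <- overlap_consensus(scan2, fx$scan, fx$G,
                               top_region_frac = 0.35, top_snp_frac = 0.1,
                               window_bp = 100000, r2_threshold = 0.2)
  expect_equal(res_rev$summary$pct_in_ld, res$summary$pct_in_ld)
  expect_equal(res_rev$summary$n_pairs, res$summary$n_pairs)
})

test_that("validation replicates a causal region and respects alpha arithmetic", {
  fx <- consensus_fixture()
  cand <- fx$scan[fx$scan$chrom == "1" & fx$scan$rank_on_chrom == 1, ]
  # independent validation cohort, thinned panel
  lay <- list("1" = list(block_spec(20, rho = 0.9, maf_range = c(0.2, 0.4)),
                         block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))),
              "2" = list(block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5))))
  Gv_full <- simulate_genotypes(400, lay, bp_step = 2000, seed = 31)
  simv <- simulate_phenotype(Gv_full, n_causal = 2, per_variant_h = 0.15,
                             prevalence = 0.5, seed = 32,
                             causal_indices = c(5L, 10L))
  Gv <- make_platform_subset(Gv_full, 0.7, seed = 33)
  val <- validate_regions(cand, Gv, simv$phenotype, fx$priors, fx$cfg,
                          B = 50, alpha = 0.05, master_seed = 34)
  expect_equal(attr(val, "alpha_adj"), 0.05)
  expect_true(val$validated)
  expect_lte(val$p_emp, 0.05)
  expect_true(val$n_snps_val <= 20 && val$n_snps_val > 0)
  # 12 candidates -> alpha_adj 0.05/12
  fake <- cand[rep(1, 12), ]
  expect_equal(bonferroni_threshold(0.05, nrow(fake)), 0.05 / 12,
               tolerance = 1e-12)
  # a region mapping nowhere is reported, not an error
  nowhere <- cand
  nowhere$chrom <- "99"
  v2 <- validate_regions(nowhere, Gv, simv$phenotype, fx$priors, fx$cfg,
                         B = 10, alpha = 0.05, master_seed = 35)
  expect_false(v2$validated)
  expect_match(v2$reason, "no validation SNPs")
})

test_that("null candidate regions validate at about the nominal rate", {
  # calibration of the mean-PIP permutation p on a null validation cohort
  lay <- list("1" = list(block_spec(12, rho = 0.2, maf_range = c(0.1, 0.5))))
  ps <- vapply(1:30, function(i) {
    Gv <- simulate_genotypes(80, lay, seed = 400 + i)
    yv <- permute_phenotype(phenotype_vector(rep(c(0L, 1L), 40)), seed = 450 + i)
    cand <- data.frame(chrom = "1", rank_on_chrom = 1L,
                       start_pos = Gv$snp_meta$pos[1],
                       end_pos = Gv$snp_meta$pos[12])
    val <- validate_regions(cand, Gv, yv, bvs_priors(),
                            bvs_config(n_iter = 1000, seed = i),
                            B = 40, alpha = 0.999, master_seed = 500 + i)
    val$p_emp
  }, 0)
  # roughly uniform: mean near 0.5, no pile-up at 0
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps <= 0.1), 0.35)
})
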