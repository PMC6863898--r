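test_that("independent SNPs are uncorrelated and dosages are 0/1/2", {
  G <- simulate_genotypes(20000, list("1" = list(
    block_spec(6, rho = 0, maf_range = c(0.5, 0.5)))), seed = 11)
  expect_true(all(G$dosages %in% c(0, 1, 2)))
  cors <- cor(G$dosages)
  off <- abs(cors[upper.tri(cors)])
  expect_lt(mean(off), 0.03)
  # MAF 0.5 at n = 50000: observed frequency in [0.49, 0.5] after orientation
  G2 <- simulate_genotypes(50000, list("1" = list(
    block_spec(3, rho = 0, maf_range = c(0.5, 0.5)))), seed = 12)
  freq <- colMeans(G2$dosages) / 2
  expect_true(all(freq >= 0.49 & freq <= 0.5))
})

test_that("high-rho blocks reproduce the Monte-Carlo dosage r2", {
  # independent oracle: 1e6 haplotype pairs by the same thresholding rule
  oracle_r2 <- local({
    set.seed(999)
    nh <- 1e6; rho <- 0.95; maf <- 0.3
    shared <- rnorm(nh)
    u1 <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(nh)
    u2 <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(nh)
    q <- qnorm(maf)
    cor(as.numeric(u1 < q), as.numeric(u2 < q))^2
  })
  r2s <- vapply(c(21, 22, 23), function(s) {
    G <- simulate_genotypes(20000, list("1" = list(
      block_spec(2, rho = 0.95, maf_range = c(0.3, 0.3)))), seed = s)
    cor(G$dosages[, 1], G$dosages[, 2])^2
  }, 0)
  expect_true(all(r2s > 0.5))
  expect_true(all(abs(r2s - oracle_r2) < 0.05))
  # r2 stable across seeds
  expect_lt(max(r2s) - min(r2s), 0.05)
})

test_that("within-block r2 grows with rho; between-block r2 is null", {
  r2_at <- function(rho) {
    G <- simulate_genotypes(20000, list("1" = list(
      block_spec(2, rho = rho, maf_range = c(0.3, 0.3)))), seed = 5)
    cor(G$dosages[, 1], G$dosages[, 2])^2
  }
  expect_true(r2_at(0.9) > r2_at(0.5) && r2_at(0.5) > r2_at(0.1))
  G <- simulate_genotypes(20000, list("1" = list(
    block_spec(2, rho = 0.9, maf_range = c(0.3, 0.3)),
    block_spec(2, rho = 0.9, maf_range = c(0.3, 0.3)))), seed = 6)
  expect_lt(cor(G$dosages[, 1], G$dosages[, 3])^2, 0.001)
})

test_that("generator input validation and reproducibility", {
  expect_error(simulate_genotypes(1, list("1" = list(block_spec(3)))), "two subjects")
  expect_error(simulate_genotypes(10, list()), "empty")
  expect_error(block_spec(3, maf_range = c(0, 0.5)), "\\(0, 0.5\\]")
  expect_error(block_spec(3, maf_range = c(0.1, 0.6)), "\\(0, 0.5\\]")
  expect_error(block_spec(3, rho = 1), "rho")
  lay <- list("1" = list(block_spec(8, rho = 0.4)))
  expect_identical(simulate_genotypes(50, lay, seed = 3),
                   simulate_genotypes(50, lay, seed = 3))
  # positions strictly increasing and evenly spaced
  G <- simulate_genotypes(10, lay, bp_start = 1000, bp_step = 250, seed = 1)
  expect_equal(G$snp_meta$pos, 1000 + 250 * (0:7))
})

test_that("null phenotype shows no association and defaults match the polygenic scale", {
  G <- simulate_genotypes(5000, list("1" = list(
    block_spec(20, rho = 0.2, maf_range = c(0.1, 0.5)))), seed = 31)
  sim <- simulate_phenotype(G, n_causal = 0, prevalence = 0.5, seed = 32)
  y <- as.numeric(sim$phenotype)
  r <- apply(G$dosages, 2, function(x) cor(x, y))
  expect_lt(abs(mean(r)), 0.01)
  expect_identical(sim$truth$causal_indices, integer(0))
  # documented default: 0.17% of liability variance per causal variant
  expect_equal(formals(simulate_phenotype)$per_variant_h, 0.0017)
})

test_that("case-control dosage shift matches the liability-model integration", {
  h <- 0.3
  G <- simulate_genotypes(50000, list("1" = list(
    block_spec(1, rho = 0, maf_range = c(0.3, 0.3)))), seed = 41)
  sim <- simulate_phenotype(G, n_causal = 1, per_variant_h = h,
                            prevalence = 0.5, seed = 42, causal_indices = 1L)
  d <- G$dosages[, 1]; y <- as.numeric(sim$phenotype)
  observed <- mean(d[y == 1]) - mean(d[y == 0])
  # oracle: integrate P(case | dosage) over the empirical dosage distribution
  beta <- abs(sim$truth$effects)
  sgn <- sign(sim$truth$effects)
  xs <- sort(unique(d))
  pd <- as.numeric(table(factor(d, levels = xs))) / length(d)
  xstd <- sgn * (xs - mean(d)) / sd(d)
  p_case <- pnorm(beta * xstd)          # threshold 0 at prevalence 1/2
  e_case <- sum(xs * pd * p_case) / sum(pd * p_case)
  e_ctrl <- sum(xs * pd * (1 - p_case)) / sum(pd * (1 - p_case))
  expect_lt(abs(observed - (e_case - e_ctrl)), 0.02)
})

test_that("liability variance decomposition holds at large n", {
  G <- simulate_genotypes(20000, list("1" = list(
    block_spec(40, rho = 0, maf_range = c(0.1, 0.5)))), seed = 51)
  n_causal <- 10; h <- 0.02
  # rebuild the genetic component from the reported truth
  sim <- simulate_phenotype(G, n_causal = n_causal, per_variant_h = h,
                            prevalence = 0.3, seed = 52)
  Xc <- scale(G$dosages[, sim$truth$causal_indices])
  genetic <- drop(Xc %*% sim$truth$effects)
  total <- var(genetic) + 1
  expect_lt(abs(var(genetic) / total - n_causal * h) / (n_causal * h), 0.1)
  expect_equal(sum(sim$truth$per_variant_h), n_causal * h, tolerance = 1e-6)
})

test_that("balanced sampling equalises cases and controls", {
  G <- simulate_genotypes(8000, list("1" = list(
    block_spec(10, rho = 0, maf_range = c(0.2, 0.5)))), seed = 61)
  sim <- simulate_phenotype(G, n_causal = 2, per_variant_h = 0.01,
                            prevalence = 0.1, balanced = TRUE, seed = 62)
  y <- as.numeric(sim$phenotype)
  expect_equal(sum(y == 1), sum(y == 0))
  expect_equal(length(sim$subjects), length(y))
  expect_true(all(sim$subjects %in% seq_len(8000)))
})

test_that("phenotype argument validation", {
  G <- tiny_panel(50)
  expect_error(simulate_phenotype(G, 1, per_variant_h = 1), "per_variant_h")
  expect_error(simulate_phenotype(G, 2, prevalence = 0), "prevalence")
  expect_error(simulate_phenotype(G, n_snps(G) + 1L), "exceeds")
})

test_that("missingness injection is binomial, reversible at rate 0, and guarded", {
  G <- simulate_genotypes(1000, list("1" = list(
    block_spec(100, rho = 0, maf_range = c(0.2, 0.5)))), seed = 71)
  expect_identical(inject_missing(G, 0), G)
  Gm <- inject_missing(G, 0.1, seed = 72)
  frac <- mean(Gm$missing_mask)
  ntot <- length(Gm$missing_mask)
  ci <- qbinom(c(0.005, 0.995), ntot, 0.1) / ntot
  expect_true(frac >= ci[1] && frac <= ci[2])
  # observed entries unchanged, masked entries NA
  expect_true(all(is.na(Gm$dosages[Gm$missing_mask])))
  expect_identical(Gm$dosages[!Gm$missing_mask], G$dosages[!Gm$missing_mask])
  G2 <- simulate_genotypes(2, list("1" = list(block_spec(5, maf_range = c(0.4, 0.5)))),
                           seed = 73)
  expect_error(inject_missing(G2, 0.999, seed = 74), "cannot keep one observed")
  expect_error(inject_missing(G, 1), "rate")
})

test_that("platform subsets keep order and overlap like independent draws", {
  G <- simulate_genotypes(100, list("1" = list(
    block_spec(1000, rho = 0, maf_range = c(0.1, 0.5)))), seed = 81)
  expect_identical(make_platform_subset(G, 1, seed = 1)$snp_meta, G$snp_meta)
  S <- make_platform_subset(G, 0.5, seed = 82)
  expect_equal(n_snps(S), 500)
  expect_true(all(S$snp_meta$pos %in% G$snp_meta$pos))
  expect_false(is.unsorted(S$snp_meta$pos))
  S2 <- make_platform_subset(G, 0.5, seed = 83)
  overlap <- length(intersect(S$snp_meta$snp_id, S2$snp_meta$snp_id)) / 1000
  expect_lt(abs(overlap - 0.25), 0.05)   # keep_fraction^2 of the panel
  expect_error(make_platform_subset(G, 0), "keep_fraction")
})
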