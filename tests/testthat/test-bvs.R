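test_that("marginal likelihood: empty model reduces to the intercept-only closed form", {
  set.seed(1)
  r <- rnorm(7, sd = 1.3)
  expect_equal(log_marginal_likelihood(r, NULL, h = 0.5, snp_variances = numeric(0)),
               intercept_only_logml(r), tolerance = 1e-12)
})

test_that("marginal likelihood matches brute-force quadrature", {
  # n = 5, one SNP, fixed h: integrate the likelihood over (mu, beta) numerically
  x <- c(0, 1, 2, 1, 0)
  r <- c(0.3, -0.2, 1.1, 0.5, -0.7)
  h <- 0.005
  s2 <- var(x)
  sa2 <- h / ((1 - h) * s2)
  lik <- function(mu, beta)
    exp(sum(dnorm(r - mu - beta * x, log = TRUE))) *
      dnorm(mu, 0, 10) * dnorm(beta, 0, sqrt(sa2))
  inner <- function(mu) vapply(mu, function(m)
    integrate(function(b) vapply(b, function(bb) lik(m, bb), 0),
              -10 * sqrt(sa2), 10 * sqrt(sa2),
              rel.tol = 1e-12, abs.tol = 0)$value, 0)
  quad <- integrate(inner, -60, 60, rel.tol = 1e-12, abs.tol = 0)$value
  expect_equal(log_marginal_likelihood(r, cbind(x), h, s2),
               log(quad), tolerance = 1e-6)
})

test_that("marginal likelihood is invariant to rescaling a SNP with its variance", {
  set.seed(2)
  x <- rbinom(30, 2, 0.3); r <- rnorm(30)
  for (cc in c(0.1, 3, 25)) {
    expect_equal(
      log_marginal_likelihood(r, cbind(x), 0.004, var(x)),
      log_marginal_likelihood(r, cbind(cc * x), 0.004, cc^2 * var(x)),
      tolerance = 1e-10)
  }
  expect_error(log_marginal_likelihood(r, cbind(x), 1.2, var(x)), "h must be")
  expect_error(log_marginal_likelihood(r, cbind(rep(1, 30)), 0.01, 0),
               "zero-variance")
})

test_that("gamma frequencies match the exhaustively enumerated posterior", {
  # 3 SNPs, n = 20, continuous trait, h fixed on a single grid point:
  # the chain's inclusion frequencies must converge to the posterior
  # computed by direct enumeration of all 2^3 models.
  set.seed(3)
  X <- matrix(rbinom(60, 2, 0.35), 20, 3)
  X[, 2] <- pmin(2, X[, 1] + rbinom(20, 1, 0.2))  # correlated pair
  y <- 0.8 * X[, 1] + rnorm(20)
  priors <- bvs_priors(max_model_size = 3)
  y_std <- as.numeric(scale(y))
  truth <- enumerate_pips(X, y_std, h_grid = 0.1, priors = priors)
  fit <- run_bvs(X, y, priors,
                 bvs_config(n_iter = 2e5, thin = 10, seed = 4,
                            trait_mode = "continuous", h_grid = 0.1))
  expect_lt(max(abs(unname(fit$pip) - truth)), 0.02)
})

test_that("model-size cap and degenerate moves keep the chain valid", {
  set.seed(5)
  X <- matrix(rbinom(200, 2, 0.4), 20, 10)
  y <- rnorm(20)
  priors <- bvs_priors(max_model_size = 2)
  cfg <- bvs_config(trait_mode = "continuous")
  # start at the cap; the inclusion count may never exceed it
  st <- list(gamma = c(1L, 2L), h = 0.005, log10_pi = -0.8)
  sizes <- integer(200)
  for (i in 1:200) {
    st <- bvs_step(X, y, priors, cfg, state = st, n_steps = 1, seed = 100 + i)
    sizes[i] <- length(st$gamma)
    expect_true(all(st$gamma >= 1 & st$gamma <= 10))
    expect_true(!anyDuplicated(st$gamma))
    expect_true(st$h >= priors$h_min && st$h <= priors$h_max)
  }
  expect_lte(max(sizes), 2L)
  # remove/switch proposed on an empty model: chain stays valid
  st <- list(gamma = integer(0), h = 0.005, log10_pi = -0.8)
  for (i in 1:50) {
    st <- bvs_step(X, y, priors, cfg, state = st, n_steps = 1, seed = 300 + i)
    expect_lte(length(st$gamma), 2L)
  }
})

test_that("PIPs are probabilities, sum_pip is capped, and runs are deterministic", {
  G <- tiny_panel(80, seed = 12)
  y <- phenotype_vector(rep(c(0L, 1L), 40))
  cfg <- bvs_config(n_iter = 3000, seed = 9, n_chains = 2)
  fit <- run_bvs(G, y, config = cfg)
  expect_true(all(fit$pip >= 0 & fit$pip <= 1))
  expect_equal(fit$sum_pip, sum(fit$pip))
  expect_equal(fit$mean_pip, fit$sum_pip / n_snps(G))
  expect_lte(fit$sum_pip, bvs_priors()$max_model_size)
  fit2 <- run_bvs(G, y, config = cfg)
  expect_identical(fit$pip, fit2$pip)
  expect_identical(fit$traces, fit2$traces)
  # different seed gives a different (but valid) realisation
  fit3 <- run_bvs(G, y, config = bvs_config(n_iter = 3000, seed = 10))
  expect_false(identical(fit$traces[[1]]$h, fit3$traces[[1]]$h))
})

test_that("null phenotypes keep the region statistic prior-dominated", {
  set.seed(20)
  sums <- vapply(1:50, function(i) {
    G <- simulate_genotypes(100, list("1" = list(
      block_spec(50, rho = 0.3, maf_range = c(0.1, 0.5)))), seed = 600 + i)
    y <- phenotype_vector(sample(rep(c(0L, 1L), 50)))
    run_bvs(G, y, config = bvs_config(n_iter = 2000, seed = i))$sum_pip
  }, 0)
  expect_lte(max(sums), 5)            # hard cap
  # null regions stay near the prior's expected model size, below the cap
  expect_lt(median(sums), 5)
})

test_that("an information-free response returns the uniform prior on h", {
  set.seed(21)
  X <- matrix(rbinom(500, 2, 0.3), 50, 10)
  y <- rnorm(50)                      # pure noise: model stays empty
  pr <- bvs_priors()
  fit <- run_bvs(X, y, pr, bvs_config(n_iter = 1e6, thin = 10, seed = 22,
                                      trait_mode = "continuous"))
  hs <- fit$traces[[1]]$h
  ks <- suppressWarnings(ks.test(hs, "punif", pr$h_min, pr$h_max))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("a strong causal SNP is recovered as the region's top PIP", {
  hits <- vapply(1:20, function(rep) {
    G <- simulate_genotypes(500, list("1" = list(
      block_spec(20, rho = 0.4, maf_range = c(0.1, 0.5)))), seed = 700 + rep)
    sim <- simulate_phenotype(G, n_causal = 1, per_variant_h = 0.3,
                              prevalence = 0.5, seed = 800 + rep)
    fit <- run_bvs(G, sim$phenotype, config = bvs_config(n_iter = 5000, seed = rep))
    which.max(fit$pip) == sim$truth$causal_indices
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("gelman_rubin follows the PSRF formula and flags degeneracy", {
  x <- rnorm(1000)
  expect_equal(as.numeric(gelman_rubin(list(x, x))), sqrt(999 / 1000),
               tolerance = 1e-12)
  set.seed(30)
  a <- rnorm(1000); b <- rnorm(1000, mean = 5)
  g <- gelman_rubin(list(a, b))
  # independent direct evaluation of the same formula
  W <- mean(c(var(a), var(b)))
  Bn <- var(c(mean(a), mean(b)))
  expect_equal(as.numeric(g), sqrt(999 / 1000 + Bn / W), tolerance = 1e-12)
  expect_gt(as.numeric(g), 1.04)
  expect_warning(gz <- gelman_rubin(list(rep(1, 20), rnorm(20))), "zero variance")
  expect_true(attr(gz, "zero_variance"))
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "too short")
  expect_error(gelman_rubin(list(rnorm(20))), "two chains")
})

test_that("converged two-chain runs pass the 1.04 bound on synthetic data", {
  G <- simulate_genotypes(300, list("1" = list(
    block_spec(40, rho = 0.5, maf_range = c(0.1, 0.5)))), seed = 44)
  sim <- simulate_phenotype(G, n_causal = 1, per_variant_h = 0.05,
                            prevalence = 0.5, seed = 45)
  fit <- run_bvs(G, sim$phenotype,
                 config = bvs_config(n_iter = 2e4, n_chains = 2, seed = 46))
  expect_lt(fit$gelman_rubin[["h"]], 1.04)
  expect_lt(fit$gelman_rubin[["log_joint"]], 1.04)
})

test_that("degenerate inputs are rejected; monomorphic SNPs are held out", {
  G <- tiny_panel(30)
  expect_error(run_bvs(G, rep(1L, 30)), "constant")
  expect_error(run_bvs(G, rep(0.7, 30),
                       config = bvs_config(trait_mode = "continuous")),
               "constant")
  expect_error(run_bvs(G$dosages[, 0, drop = FALSE], rep(c(0L, 1L), 15)),
               "empty region")
  Xm <- cbind(G$dosages[, 1:3], mono = rep(2, 30))
  fit <- run_bvs(Xm, rep(c(0L, 1L), 15), config = bvs_config(n_iter = 1000, seed = 2))
  expect_equal(unname(fit$pip[4]), 0)
  expect_equal(fit$dropped, 4L)
})

test_that("fit methods expose coefficients, predictions and simulations", {
  G <- simulate_genotypes(300, list("1" = list(
    block_spec(10, rho = 0.2, maf_range = c(0.2, 0.5)))), seed = 50)
  sim <- simulate_phenotype(G, n_causal = 1, per_variant_h = 0.25,
                            prevalence = 0.5, seed = 51, causal_indices = 5L)
  fit <- run_bvs(G, sim$phenotype, config = bvs_config(n_iter = 5000, seed = 52))
  cf <- coef(fit)
  expect_length(cf, 11L)
  expect_equal(names(cf)[1], "(Intercept)")
  # the causal SNP carries the dominant model-averaged effect
  expect_equal(which.max(abs(cf[-1])), 5L, ignore_attr = TRUE)
  pr_link <- predict(fit, G)
  pr_resp <- predict(fit, G, type = "response")
  expect_true(all(pr_resp > 0 & pr_resp < 1))
  expect_equal(pr_resp, pnorm(pr_link))
  # fitted probabilities separate cases from controls
  expect_gt(mean(fitted(fit)[fit$y == 1]), mean(fitted(fit)[fit$y == 0]))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  ss <- simulate(fit, nsim = 3, seed = 53, newdata = G)
  expect_equal(dim(ss), c(300L, 3L))
  expect_true(all(unlist(ss) %in% 0:1))
  expect_output(print(fit), "bvs_fit")
  expect_output(print(summary(fit)), "sum of PIPs")
})
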