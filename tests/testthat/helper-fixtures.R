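# Shared fixture builders.  Everything is generated in code; no data files.

# A small multi-block genotype panel on one or two chromosomes.
tiny_panel <- function(n = 200, seed = 42,
                       layout = list(
                         "1" = list(block_spec(6, rho = 0.7, maf_range = c(0.2, 0.4)),
                                    block_spec(4, rho = 0, maf_range = c(0.1, 0.5))),
                         "2" = list(block_spec(5, rho = 0.3, maf_range = c(0.05, 0.5))))) {
  simulate_genotypes(n, layout, seed = seed)
}

# Hand-written mean-genotype fixture files; returns the three paths.
write_mean_fixture <- function(dir, genotype_lines, position_lines, phenotype_lines) {
  g <- file.path(dir, "geno.txt")
  p <- file.path(dir, "pos.txt")
  y <- file.path(dir, "pheno.txt")
  writeLines(genotype_lines, g)
  writeLines(position_lines, p)
  writeLines(phenotype_lines, y)
  list(genotype = g, position = p, phenotype = y)
}

# Independent closed form for the intercept-only marginal likelihood:
# r ~ N(0, I + v0 * J) directly via the rank-one determinant/inverse.
intercept_only_logml <- function(r, v0 = 100) {
  n <- length(r)
  s <- sum(r)
  -n / 2 * log(2 * pi) - 0.5 * log(1 + n * v0) -
    0.5 * (sum(r^2) - v0 * s^2 / (1 + n * v0))
}

# Independent brute-force enumeration of the variable-selection posterior
# for a continuous response: all inclusion sets up to `cap` SNPs crossed
# with a grid of h values; the sparsity parameter pi is integrated out
# numerically over its log10-uniform prior.  Returns per-SNP inclusion
# probabilities.  Deliberately does NOT reuse the package's marginal
# likelihood: the integrand is evaluated by direct 2(+k)-free closed-form
# multivariate-normal algebra on the covariance matrix.
enumerate_pips <- function(X, y_std, h_grid, priors) {
  p <- ncol(X)
  v0 <- priors$intercept_var
  sv <- apply(X, 2, var)
  lb <- 10^regionbvs:::log10_pi_bounds(priors, p)   # pi box
  cap <- priors$max_model_size

  logml_direct <- function(idx, h) {
    n <- nrow(X)
    Sigma <- diag(n) + v0 * matrix(1, n, n)
    if (length(idx)) {
      sa2 <- h / ((1 - h) * sum(sv[idx]))
      Xg <- X[, idx, drop = FALSE]
      Sigma <- Sigma + sa2 * tcrossprod(Xg)
    }
    ch <- chol(Sigma)
    -n / 2 * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, y_std, transpose = TRUE)^2)
  }
  # prior mass of an inclusion set of size k, integrating pi over its prior
  l10 <- log10(lb)
  prior_k <- function(k) {
    if (l10[2] - l10[1] < 1e-12) {
      pi0 <- lb[1]
      return(pi0^k * (1 - pi0)^(p - k))
    }
    stats::integrate(function(l) {
      pi <- 10^l
      pi^k * (1 - pi)^(p - k)
    }, l10[1], l10[2], rel.tol = 1e-10)$value / (l10[2] - l10[1])
  }

  sets <- list(integer(0))
  for (k in seq_len(cap))
    sets <- c(sets, combn(p, k, simplify = FALSE))
  logw <- vapply(sets, function(idx) {
    ml <- vapply(h_grid, function(h) logml_direct(idx, h), 0)
    m <- max(ml)
    m + log(mean(exp(ml - m))) + log(prior_k(length(idx)))
  }, 0)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  pip <- numeric(p)
  for (s in seq_along(sets)) pip[sets[[s]]] <- pip[sets[[s]]] + w[s]
  pip
}

# Independent brute-force window enumerator: stepped starts plus an
# end-anchored final window whenever the last stepped window falls short.
brute_windows <- function(n, window, step) {
  if (n <= window) return(cbind(start = 1L, end = as.integer(n)))
  starts <- integer(0); s <- 1L
  while (s + window - 1L <= n) { starts <- c(starts, s); s <- s + step }
  if (max(starts + window - 1L) < n) starts <- c(starts, n - window + 1L)
  cbind(start = starts, end = starts + window - 1L)
}
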