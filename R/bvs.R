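# Sparse Bayesian variable-selection regression over one SNP region:
# spike-and-slab prior on inclusion, uniform prior on the variance explained
# h, log-uniform prior on the sparsity pi, probit link via latent-liability
# data augmentation.  The MCMC engine lives in src/bvs_mcmc.cpp; this file
# holds the user-facing fitting interface.

#' Priors for the variable-selection sampler
#'
#' @param h_min,h_max bounds of the uniform prior on \code{h}, the proportion
#'   of phenotypic variance explained by the included SNPs.  Defaults 0.0001
#'   and 0.01 (i.e. 0.01--1\%), the scale appropriate for a highly polygenic
#'   trait where any one region carries a tiny fraction of the heritability.
#' @param target_size_min,target_size_max bounds on the expected number of
#'   relevant SNPs per 1000-SNP region (defaults 1 and 5); they set the
#'   log-uniform prior on the per-SNP inclusion probability \code{pi} after
#'   scaling by the actual region size.
#' @param max_model_size hard cap on the number of SNPs included at once
#'   (default 5); proposals beyond the cap are rejected outright.
#' @param intercept_var variance of the vague zero-mean normal prior on the
#'   intercept (default 100).
#' @return a \code{"bvs_priors"} list.
#' @export
bvs_priors <- function(h_min = 1e-4, h_max = 0.01,
                       target_size_min = 1, target_size_max = 5,
                       max_model_size = 5, intercept_var = 100) {
  if (!(h_min > 0 && h_min < h_max && h_max < 1))
    stop_input("need 0 < h_min < h_max < 1")
  if (!(target_size_min >= 1 && target_size_min <= target_size_max))
    stop_input("need 1 <= target_size_min <= target_size_max")
  if (max_model_size < 1) stop_input("max_model_size must be >= 1")
  if (intercept_var <= 0) stop_input("intercept_var must be positive")
  structure(list(h_min = h_min, h_max = h_max,
                 target_size_min = target_size_min,
                 target_size_max = target_size_max,
                 max_model_size = as.integer(max_model_size),
                 intercept_var = intercept_var),
            class = "bvs_priors")
}

#' MCMC configuration for the variable-selection sampler
#'
#' @param n_iter sweeps per chain (>= 1000).  10^6 is the full-scale setting
#'   for 1000-SNP regions; 10^5 is a practical default for testing-scale
#'   regions.
#' @param burn_in fraction of sweeps discarded (default 0.2).
#' @param thin trace-recording interval (default 10); posterior inclusion
#'   probabilities use every post-burn-in sweep regardless.
#' @param n_chains independent chains (>= 1); with two or more chains the
#'   Gelman-Rubin diagnostic is computed on the \code{h} and log-joint traces.
#' @param seed integer master seed; chain seeds are derived from it.
#' @param trait_mode \code{"binary"} (probit, the default) or
#'   \code{"continuous"} (identity link on a standardised response).
#' @param h_grid optional numeric vector restricting \code{h} to a finite
#'   grid with uniform prior over the grid points (used mainly to compare
#'   the sampler against exhaustive enumeration).
#' @param h_prop_sd,pi_prop_sd random-walk proposal standard deviations for
#'   \code{h} and \code{log10 pi}; \code{h_prop_sd} defaults to a tenth of
#'   the prior range.
#' @return a \code{"bvs_config"} list.
#' @export
bvs_config <- function(n_iter = 1e5, burn_in = 0.2, thin = 10L,
                       n_chains = 1L, seed = 1L,
                       trait_mode = c("binary", "continuous"),
                       h_grid = NULL, h_prop_sd = NULL, pi_prop_sd = 0.25) {
  trait_mode <- match.arg(trait_mode)
  if (n_iter < 1000) stop_input("n_iter must be >= 1000")
  if (burn_in < 0 || burn_in >= 1) stop_input("burn_in fraction must be in [0, 1)")
  if (thin < 1) stop_input("thin must be >= 1")
  if (n_chains < 1) stop_input("n_chains must be >= 1")
  if (!is.null(h_grid) && (!length(h_grid) || any(h_grid <= 0 | h_grid >= 1)))
    stop_input("h_grid values must lie in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = burn_in,
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), trait_mode = trait_mode,
                 h_grid = h_grid, h_prop_sd = h_prop_sd,
                 pi_prop_sd = pi_prop_sd),
            class = "bvs_config")
}

#' Log marginal likelihood of a response under one inclusion set
#'
#' Closed form of \eqn{\log \int p(r \mid \mu, \beta)\, p(\beta \mid h)\,
#' p(\mu)\, d\mu\, d\beta} with unit residual variance,
#' \eqn{\beta_j \sim N(0, \sigma_a^2)} where
#' \eqn{\sigma_a^2 = h / ((1-h) \sum_{j \in \gamma} s_j^2)}, and a vague
#' zero-mean normal prior on the intercept.  With an empty inclusion set the
#' expression reduces to the intercept-only marginal and does not depend on
#' \code{h}.
#'
#' @param response numeric vector (the latent liability in probit mode, the
#'   standardised trait in continuous mode).
#' @param X_gamma matrix of included-SNP dosage columns, or NULL for the
#'   empty set.
#' @param h variance-explained parameter in (0, 1).
#' @param snp_variances per-SNP sample variances \eqn{s_j^2} of the included
#'   columns; all must be positive.
#' @param intercept_var intercept prior variance (default 100).
#' @return the log marginal density (a finite scalar).
#' @export
log_marginal_likelihood <- function(response, X_gamma, h, snp_variances,
                                    intercept_var = 100) {
  n <- length(response)
  k <- if (is.null(X_gamma)) 0L else ncol(as.matrix(X_gamma))
  if (k > 0L) {
    if (h <= 0 || h >= 1) stop_input("h must be in (0, 1)")
    if (length(snp_variances) != k)
      stop_input("snp_variances length != number of included SNPs")
    if (any(snp_variances <= 0))
      stop_input("zero-variance SNP in the inclusion set")
    sigma_a2 <- h / ((1 - h) * sum(snp_variances))
    W <- cbind(1, as.matrix(X_gamma))
    v <- c(intercept_var, rep(sigma_a2, k))
  } else {
    W <- matrix(1, n, 1)
    v <- intercept_var
  }
  A <- crossprod(W) + diag(1 / v, k + 1L)
  b <- crossprod(W, response)
  cf <- chol(A)
  quad <- sum(backsolve(cf, b, transpose = TRUE)^2)
  -n / 2 * log(2 * pi) -
    0.5 * (2 * sum(log(diag(cf))) + sum(log(v))) -
    0.5 * (sum(response^2) - quad)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard PSRF \eqn{\sqrt{(n-1)/n + B/(n W)}} with \eqn{B} the
#' between-chain and \eqn{W} the within-chain variance (no rank
#' normalisation).  Values near 1 indicate the chains are sampling the same
#' distribution; the convergence bound used throughout this package is 1.04.
#'
#' @param traces list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.  At least two chains of length >= 10.
#' @return the PSRF.  If any chain has zero variance the value carries the
#'   attribute \code{zero_variance = TRUE} and a warning is issued.
#' @export
gelman_rubin <- function(traces) {
  if (is.matrix(traces))
    traces <- lapply(seq_len(ncol(traces)), function(j) traces[, j])
  m <- length(traces)
  if (m < 2L) stop_input("need at least two chains")
  len <- lengths(traces)
  if (length(unique(len)) != 1L) stop_input("chains have unequal lengths")
  nlen <- len[1L]
  if (nlen < 10L) stop_input("chains too short (length < 10)")
  mu <- vapply(traces, mean, 0)
  vv <- vapply(traces, stats::var, 0)
  W <- mean(vv)
  B_over_n <- stats::var(mu)        # B = n * var(chain means)
  flag <- any(vv == 0)
  val <- if (W > 0) sqrt((nlen - 1) / nlen + B_over_n / W)
         else if (B_over_n == 0) sqrt((nlen - 1) / nlen)
         else Inf
  if (flag) {
    warning("chain(s) with zero variance in gelman_rubin")
    attr(val, "zero_variance") <- TRUE
  }
  val
}

# Sparsity-prior box on log10(pi) implied by the target model-size range,
# scaled by the number of SNPs actually offered to the sampler.
log10_pi_bounds <- function(priors, p) {
  pi_hi <- min(priors$target_size_max / p, 1 - 1e-6)
  pi_lo <- min(priors$target_size_min / p, pi_hi)
  c(log10(pi_lo), log10(pi_hi))
}

#' Fit the region-level Bayesian variable-selection model
#'
#' Runs the spike-and-slab MCMC over one SNP region and reports per-SNP
#' posterior inclusion probabilities (PIPs), their sum and mean (the region's
#' association statistics), parameter traces and, with two or more chains,
#' Gelman-Rubin diagnostics.  Each sweep proposes an add, remove or switch
#' move on the inclusion set (Metropolis-Hastings on the analytically
#' marginalised model), random-walk updates of \code{h} and
#' \code{log10 pi} within their prior boxes, and -- for binary traits -- a
#' Gibbs draw of the coefficients and the latent probit liabilities.
#'
#' Monomorphic (zero-variance) SNP columns cannot enter the model; they are
#' kept out of the sampler and reported with PIP 0.
#'
#' @param G_region a [genotype_matrix()] (typically one window of a larger
#'   matrix, see [subset_snps()]) or a plain dosage matrix; no missing
#'   entries.
#' @param y a [phenotype_vector()] for binary traits, or a numeric vector
#'   for continuous traits (standardised internally).
#' @param priors a [bvs_priors()].
#' @param config a [bvs_config()].
#' @return an object of class \code{"bvs_fit"}; see
#'   [summary.bvs_fit()], [coef.bvs_fit()], [predict.bvs_fit()],
#'   [plot.bvs_fit()].
#' @export
run_bvs <- function(G_region, y, priors = bvs_priors(), config = bvs_config()) {
  if (inherits(G_region, "genotype_matrix")) {
    X <- G_region$dosages
    meta <- G_region$snp_meta
    sv <- G_region$snp_variance
  } else {
    X <- as.matrix(G_region)
    if (ncol(X) < 1L) stop_input("empty region")
    meta <- data.frame(snp_id = colnames(X) %||% paste0("snp", seq_len(ncol(X))),
                       chrom = "1", pos = seq_len(ncol(X)),
                       minor = NA_character_, major = NA_character_,
                       stringsAsFactors = FALSE)
    sv <- NULL
  }
  if (ncol(X) < 1L) stop_input("empty region")
  if (anyNA(X)) stop_input("region contains missing dosages; impute first")
  if (nrow(X) != length(y)) stop_input("phenotype not aligned with subjects")
  if (is.null(sv) || anyNA(sv)) sv <- apply(X, 2L, stats::var)

  binary <- config$trait_mode == "binary"
  if (binary) {
    y <- as.numeric(phenotype_vector(y))   # validates 0/1 and non-constancy
  } else {
    y <- as.numeric(y)
    if (stats::sd(y) == 0) stop_input("constant continuous response")
    y <- as.numeric(scale(y))
  }

  p_all <- ncol(X)
  usable <- which(sv > 0)
  if (!length(usable)) stop_input("region has no polymorphic SNPs")
  p_used <- length(usable)

  lb <- log10_pi_bounds(priors, p_used)
  burn <- as.integer(floor(config$burn_in * config$n_iter))
  h_prop <- config$h_prop_sd %||% ((priors$h_max - priors$h_min) / 10)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(config$seed, ch), {
      .bvs_mcmc_cpp(X[, usable, drop = FALSE], y, binary, sv[usable],
                    priors$h_min, priors$h_max, lb[1L], lb[2L],
                    priors$max_model_size, priors$intercept_var,
                    config$n_iter, burn, config$thin,
                    as.numeric(config$h_grid %||% numeric(0)),
                    h_prop, config$pi_prop_sd,
                    list(), FALSE)
    })
  }

  pip <- rep(0, p_all)
  coefs <- rep(0, p_all)
  for (ch in chains) {
    pip[usable] <- pip[usable] + ch$pip / config$n_chains
    coefs[usable] <- coefs[usable] + ch$beta_mean / config$n_chains
  }
  names(pip) <- meta$snp_id
  mu_mean <- mean(vapply(chains, `[[`, 0, "mu_mean"))

  traces <- lapply(chains, function(ch)
    data.frame(h = ch$trace_h, log10_pi = ch$trace_log10_pi,
               model_size = ch$trace_model_size,
               log_joint = ch$trace_log_joint))
  gr <- NULL
  if (config$n_chains >= 2L) {
    gr <- c(h = as.numeric(gelman_rubin(lapply(traces, `[[`, "h"))),
            log_joint = as.numeric(gelman_rubin(lapply(traces, `[[`, "log_joint"))))
  }
  acc <- t(vapply(chains, function(ch) {
    r <- ifelse(ch$proposed > 0, ch$accepted / ch$proposed, NA_real_)
    stats::setNames(r, c("add", "remove", "switch", "h", "pi"))
  }, numeric(5)))

  eta <- drop(mu_mean + X %*% coefs)
  structure(list(
    pip = pip, sum_pip = sum(pip), mean_pip = sum(pip) / p_all,
    coefficients = c("(Intercept)" = mu_mean, stats::setNames(coefs, meta$snp_id)),
    linear_predictor = eta, y = y,
    traces = traces, gelman_rubin = gr, acceptance = acc,
    priors = priors, config = config, snp_meta = meta,
    n = nrow(X), p = p_all, dropped = setdiff(seq_len(p_all), usable),
    trait_mode = config$trait_mode,
    call = match.call()
  ), class = "bvs_fit")
}

#' Advance the sampler by a few sweeps from a given state
#'
#' Low-level access to the Markov transition kernel, mainly useful for
#' studying the chain itself (e.g. that the model-size cap is enforced, or
#' that degenerate moves leave the state valid).  The returned state can be
#' fed back in to continue the chain.
#'
#' @param X dosage matrix (no missing values, all columns polymorphic).
#' @param y response as in [run_bvs()].
#' @param priors,config as in [run_bvs()] (\code{config$n_chains} ignored).
#' @param state optional list with elements \code{gamma} (1-based included
#'   indices), \code{h}, \code{log10_pi} and, for binary traits, \code{z};
#'   missing pieces are initialised as in [run_bvs()].
#' @param n_steps number of sweeps to advance (default 1).
#' @param seed integer seed.
#' @return list with the new \code{gamma} (1-based), \code{h},
#'   \code{log10_pi}, \code{mu}, \code{beta} and \code{z}.
#' @export
bvs_step <- function(X, y, priors = bvs_priors(), config = bvs_config(),
                     state = NULL, n_steps = 1L, seed = 1L) {
  X <- as.matrix(X)
  binary <- config$trait_mode == "binary"
  if (binary) y <- as.numeric(phenotype_vector(y)) else y <- as.numeric(scale(y))
  sv <- apply(X, 2L, stats::var)
  if (any(sv <= 0)) stop_input("bvs_step requires polymorphic columns")
  lb <- log10_pi_bounds(priors, ncol(X))
  init <- list()
  if (!is.null(state)) {
    init <- state
    init$gamma <- as.integer(state$gamma) - 1L    # to 0-based
    init$z <- state$z
  }
  h_prop <- config$h_prop_sd %||% ((priors$h_max - priors$h_min) / 10)
  res <- with_seed(seed, {
    .bvs_mcmc_cpp(X, y, binary, sv, priors$h_min, priors$h_max,
                  lb[1L], lb[2L], priors$max_model_size, priors$intercept_var,
                  max(as.integer(n_steps), 1L), max(as.integer(n_steps), 1L), 1L,
                  numeric(0), h_prop, config$pi_prop_sd, init, TRUE)
  })
  st <- res$state
  st$gamma <- sort(as.integer(st$gamma) + 1L)
  st
}
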