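# S3 methods for fitted region models.

#' @export
print.bvs_fit <- function(x, ...) {
  cat(sprintf("<bvs_fit> %s-trait region model: %d SNPs, %d subjects\n",
              x$trait_mode, x$p, x$n))
  cat(sprintf("  chains: %d x %d sweeps (burn-in %g%%)\n",
              x$config$n_chains, x$config$n_iter, 100 * x$config$burn_in))
  cat(sprintf("  sum of PIPs: %.3f   mean PIP: %.4g\n", x$sum_pip, x$mean_pip))
  if (!is.null(x$gelman_rubin))
    cat(sprintf("  Gelman-Rubin: h %.4f, log-joint %.4f\n",
                x$gelman_rubin[["h"]], x$gelman_rubin[["log_joint"]]))
  invisible(x)
}

#' Summarise a fitted region model
#'
#' @param object a \code{"bvs_fit"}.
#' @param top number of top-PIP SNPs to tabulate (default 10).
#' @param ... unused.
#' @return a \code{"summary.bvs_fit"} list with the region statistics,
#'   convergence diagnostics, acceptance rates and the top-PIP SNP table
#'   (including the Manhattan-scale column \code{neg_log10_one_minus_pip}).
#' @export
summary.bvs_fit <- function(object, top = 10L, ...) {
  ord <- order(object$pip, decreasing = TRUE)
  idx <- utils::head(ord, top)
  tab <- data.frame(
    snp_id = object$snp_meta$snp_id[idx],
    chrom = object$snp_meta$chrom[idx],
    pos = object$snp_meta$pos[idx],
    pip = unname(object$pip[idx]),
    neg_log10_one_minus_pip = -log10(pmax(1 - unname(object$pip[idx]), 1e-6)))
  out <- list(sum_pip = object$sum_pip, mean_pip = object$mean_pip,
              gelman_rubin = object$gelman_rubin,
              acceptance = object$acceptance,
              top_snps = tab, n = object$n, p = object$p,
              n_chains = object$config$n_chains,
              dropped = object$dropped)
  class(out) <- "summary.bvs_fit"
  out
}

#' @export
print.summary.bvs_fit <- function(x, ...) {
  cat(sprintf("Region of %d SNPs, %d subjects (%d chain(s))\n", x$p, x$n, x$n_chains))
  cat(sprintf("sum of PIPs %.3f, mean PIP %.4g\n", x$sum_pip, x$mean_pip))
  if (!is.null(x$gelman_rubin))
    cat(sprintf("Gelman-Rubin PSRF: h %.4f, log-joint %.4f (bound 1.04)\n",
                x$gelman_rubin[["h"]], x$gelman_rubin[["log_joint"]]))
  if (length(x$dropped))
    cat(sprintf("%d monomorphic SNP(s) held out with PIP 0\n", length(x$dropped)))
  cat("Top SNPs by posterior inclusion probability:\n")
  print(x$top_snps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior-mean coefficients of a fitted region model
#'
#' Model-averaged posterior means of the intercept and per-SNP effects
#' (zero whenever a SNP is excluded), on the latent-liability scale for
#' binary traits and the standardised-response scale for continuous traits.
#'
#' @param object a \code{"bvs_fit"}.
#' @param ... unused.
#' @return named numeric vector, intercept first.
#' @export
coef.bvs_fit <- function(object, ...) object$coefficients

#' Predict from a fitted region model
#'
#' @param object a \code{"bvs_fit"}.
#' @param newdata a [genotype_matrix()] or dosage matrix with the region's
#'   SNPs as columns.
#' @param type \code{"link"} for the linear predictor on the latent scale,
#'   \code{"response"} for the case probability (binary traits; identical to
#'   the link for continuous traits).
#' @param ... unused.
#' @return numeric vector, one value per subject of \code{newdata}.
#' @export
predict.bvs_fit <- function(object, newdata,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "genotype_matrix")) newdata$dosages else as.matrix(newdata)
  if (ncol(X) != object$p)
    stop_input("newdata has %d SNPs, model has %d", ncol(X), object$p)
  eta <- drop(object$coefficients[1L] + X %*% object$coefficients[-1L])
  if (type == "response" && object$trait_mode == "binary") stats::pnorm(eta) else eta
}

#' @export
fitted.bvs_fit <- function(object, ...) {
  if (object$trait_mode == "binary") stats::pnorm(object$linear_predictor)
  else object$linear_predictor
}

#' Simulate phenotypes from a fitted region model
#'
#' For binary traits, draws Bernoulli outcomes at the fitted case
#' probabilities; for continuous traits, adds unit-variance normal noise to
#' the linear predictor.
#'
#' @param object a \code{"bvs_fit"}.
#' @param nsim number of replicate phenotype vectors.
#' @param seed integer seed.
#' @param newdata dosages to simulate at (see [predict.bvs_fit()]).
#' @param ... unused.
#' @return a data frame with \code{nsim} columns as [stats::simulate()].
#' @export
simulate.bvs_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  eta <- predict(object, newdata, type = "link")
  with_seed(seed, {
    sims <- replicate(nsim, {
      if (object$trait_mode == "binary")
        stats::rbinom(length(eta), 1L, stats::pnorm(eta))
      else eta + stats::rnorm(length(eta))
    })
    as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' Manhattan-style plot of per-SNP posterior inclusion probabilities
#'
#' Plots \code{-log10(1 - PIP)} against genomic position (PIPs clipped at
#' \code{1 - 1e-6} to avoid infinities), with alternating chromosome shading
#' when the region spans several chromosomes.
#'
#' @param x a \code{"bvs_fit"}.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data frame.
#' @export
plot.bvs_fit <- function(x, ...) {
  df <- data.frame(chrom = x$snp_meta$chrom, pos = x$snp_meta$pos,
                   pip = unname(x$pip))
  df$y <- -log10(pmax(1 - df$pip, 1e-6))
  manhattan_panel(df, ylab = expression(-log[10](1 - PIP)), ...)
  invisible(df)
}

#' Response residuals of a fitted region model
#' @param object a \code{"bvs_fit"}.
#' @param ... unused.
#' @return observed response minus fitted value (case probability for binary
#'   traits, standardised response for continuous traits).
#' @export
residuals.bvs_fit <- function(object, ...) object$y - fitted(object)
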