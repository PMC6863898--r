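---
title: "Region-based Bayesian variable selection for case-control GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based Bayesian variable selection for case-control GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionbvs)
```

## The problem

Single-SNP association tests look at one variant at a time and can miss
signals that are carried jointly by several nearby, partially correlated
variants. `regionbvs` implements the alternative this package is built
around: cut each chromosome into overlapping windows of a fixed number of
SNPs, fit a sparse Bayesian variable-selection (BVS) regression inside every
window, and treat the window-level *sum of posterior inclusion
probabilities* (PIPs) as the association statistic. Because the null
distribution of that statistic is not available in closed form, region-level
significance comes from a phenotype-permutation test with Bonferroni control
and early stopping, and surviving regions are re-tested in an independent
cohort.

## The regression model

Within one region of $p$ SNPs with dosage columns $x_1,\dots,x_p$ (copies of
the minor allele, mean-imputed where missing), the model for a subject's
latent liability $z_i$ is

$$ z_i = \mu + \sum_{j:\gamma_j = 1} \beta_j x_{ij} + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, 1), $$

with the binary phenotype $y_i = \mathbf{1}(z_i > 0)$ (probit link).
$\gamma \in \{0,1\}^p$ selects which SNPs are in the model. The priors are:

* $\beta_j \mid \gamma, h \sim N(0, \sigma_a^2)$ with
  $\sigma_a^2 = h \big/ \big((1-h)\sum_{j\in\gamma} s_j^2\big)$, where
  $s_j^2$ is the sample variance of dosage $j$. This ties $h$ directly to
  the proportion of liability variance explained by the included SNPs,
  given unit residual variance.
* $h \sim \mathrm{Uniform}(h_{\min}, h_{\max})$, default $10^{-4}$ to
  $10^{-2}$ (0.01%–1%). This is the right scale for a highly polygenic
  trait in which a hundred-odd loci jointly explain under a fifth of the
  variance, so a single ~1000-SNP window carries a tiny share — about
  0.17% per causal variant, which is the synthetic generator's default.
* $\gamma_j \mid \pi \sim \mathrm{Bernoulli}(\pi)$ with $\log_{10}\pi$
  uniform between $\log_{10}(L/p)$ and $\log_{10}(U/p)$, $(L, U) = (1, 5)$:
  one to five relevant SNPs expected per region, rescaled to the region's
  actual size. A hard cap $|\gamma| \le 5$ bounds the model size.
* $\mu \sim N(0, 100)$, effectively vague. Stated for reproducibility.

For a continuous trait the same model is used with the response
standardised and the identity link; the residual variance is fixed at 1 in
both modes, which is what makes $h$ interpretable as a variance fraction.

## Posterior computation

Given $(\gamma, h)$ and the (latent) response, $(\mu, \beta)$ are Gaussian
and are integrated out analytically, so the chain only has to explore
$(\gamma, h, \log_{10}\pi)$ and, for binary traits, the liabilities $z$.
One MCMC sweep is:

1. a Metropolis–Hastings move on $\gamma$, chosen uniformly among *add* (a
   uniformly random excluded SNP), *remove* (a uniformly random included
   SNP) and *switch* (one included for one excluded), accepted by the
   marginal-likelihood ratio times the $\pi$-prior ratio times the proposal
   asymmetry correction; proposals beyond the size cap are rejected
   outright, and infeasible moves (remove on an empty model) count as
   auto-rejected;
2. reflected random-walk updates of $h$ and $\log_{10}\pi$ inside their
   prior boxes (when an `h_grid` is supplied, $h$ instead proposes
   uniformly from the grid — this is what makes exact enumeration
   cross-checks possible);
3. for binary traits, a Gibbs draw of $(\mu, \beta)$ from the conjugate
   normal and of each $z_i$ from a unit-variance normal truncated to
   $(0,\infty)$ if $y_i = 1$ and $(-\infty, 0]$ otherwise.

PIPs are post-burn-in inclusion frequencies (one could instead
Rao-Blackwellise; inclusion counting is simpler and unbiased, and is the
estimator this package commits to). Defaults: 20% burn-in, thinning 10 for
traces, $10^5$ sweeps per chain at test scale; a full-scale 1000-SNP
region is run with $10^6$ sweeps. With two or more chains the sampler
reports the Gelman–Rubin potential scale reduction factor
$\sqrt{(n-1)/n + B/(nW)}$ — plain PSRF, no rank normalisation — on both the
$h$ trace and the log-joint trace; both must fall below 1.04 to call a run
converged. No covariates are fitted: multi-SNP Bayesian regressions are
comparatively robust to population stratification, and the pipeline
deliberately mirrors that design choice.

Numerical notes: the per-move marginal likelihood uses a closed form on the
$(|\gamma|+1)$-dimensional coefficient block (Cholesky on a tiny reused
buffer, in compiled code), so a sweep costs $O(n\,|\gamma|)$; monomorphic
SNP columns cannot enter the model and are reported with PIP 0; dosage
columns may be scaled arbitrarily since $\sigma_a^2$ co-scales through
$s_j^2$ (an invariance the tests assert).

## Region partition

Windows of `window` SNPs (default 1000) start every `step` SNPs (default
`window/2`, i.e. half-window overlap). A chromosome shorter than one
window becomes a single region; otherwise, if the last stepped window does
not reach the chromosome end, a final window anchored to the last `window`
SNPs is appended. The anchored rule keeps all full-chromosome windows the
same size, which keeps the sparsity prior comparable across regions; its
side effect is that up to `step - 1` SNPs near a chromosome end sit in
three windows rather than two. Regions are identified by chromosome and a
within-chromosome rank starting at 1, and carry the base-pair positions of
their first and last SNP (1-based, both ends inclusive).

## Permutation significance

The discovery statistic is the region's sum of PIPs. Each permutation
relabels the phenotype uniformly at random (case count preserved exactly)
and refits the full MCMC with a permutation-specific seed derived
deterministically from the master seed — no shortcut statistic is
substituted. With a budget of $B$ permutations (100,000 at full scale) and
a Bonferroni-adjusted level $\alpha^\ast$ ($0.1/\#\text{regions}$ in
discovery — deliberately liberal, since validation filters false
positives), the empirical p-value is $r/B$ with $r$ the number of permuted
statistics $\ge$ the observed one (ties count against significance;
$r = 0$ prints as "<1/B"; an add-one estimator is available). After every
batch (default 100) the test stops early iff even the most favourable
completion could no longer reach significance, i.e. iff
$r/B > \alpha^\ast$ already holds. This bound — rather than the running
p-value — guarantees the early-stopped decision always equals the
exhausted run's decision on the same seed stream, which the tests verify.

Validation maps each candidate region onto the independent cohort's panel
by its position interval (both ends inclusive; different genotyping
platforms share positions, not SNP panels), so the mapped region rarely has
exactly the discovery marker count; the *mean* PIP replaces the sum as the
statistic for that reason. Validation uses $\alpha = 0.05$ over the number
of candidates and 1000 permutations.

## Consensus analysis

To compare two scans without permutation testing, the top 5% of regions by
sum of PIPs are selected in each dataset, within each the top 1% of SNPs by
PIP (ceiling counts, ties broken by genomic order), and every selected SNP
of one dataset is paired with every selected SNP of the other on the same
chromosome within 100,000 bp (symmetric union, de-duplicated; not
nearest-only). Pairs are called "in LD" when their squared dosage
correlation, computed in a single designated reference genotype set that
contains both SNPs, reaches `r2_threshold`. The threshold defaults to 0.2
but is deliberately configurable: reported LD pairs in this design span
$R^2$ from roughly 0.1 to 0.9, and no single canonical cutoff exists. In
synthetic runs the reference is the full simulated panel; with real data
the user must designate a reference that carries both platforms' SNPs —
which panel to use is a genuinely open choice of the analysis, not
something the method pins down.

## The synthetic-data generator

The generator exists so that every stage above is testable without
controlled-access genotypes. It emulates exactly the features the analysis
relies on, and nothing more:

* **Genotypes.** Two haplotypes per subject; within an LD block, haplotype
  alleles come from thresholding an exchangeably correlated latent Gaussian
  (correlation `rho`) at each SNP's minor-allele-frequency quantile
  (Gaussian copula; an AR(1) option exists behind `corr = "ar1"`). Dosages
  are therefore exact 0/1/2 sums, blocks are internally correlated and
  mutually independent, and minor-allele orientation holds after
  generation. Positions are synthetic and evenly spaced — only ordering
  and distances matter downstream.
* **Phenotype.** Liability threshold model: each causal SNP contributes a
  fixed fraction (`per_variant_h`, default 0.0017) of liability variance
  through an effect placed on the empirically standardised dosage, noise
  is standard normal, and a subject is a case iff liability exceeds the
  quantile matching the prevalence. Balanced case-control designs are
  produced by subsampling equal numbers of simulated cases and controls,
  mirroring the near-balanced designs of the cohorts this protocol targets.
  With correlated causal SNPs the variance bookkeeping ignores their
  cross-covariances, so `per_variant_h` is exact for independent causal
  SNPs and approximate inside tight LD blocks.
* **Platforms.** A second genotyping platform is emulated by uniformly
  subsetting the SNP panel (`keep_fraction`); an independent validation
  cohort is a fresh simulation from the same layout with a different seed.
* **Missingness.** Entries are masked independently at a fixed rate
  (mean imputation later repairs them); a column can never lose its last
  observed genotype.

What the generator does *not* emulate: recombination-map LD decay,
population structure and admixture, genotyping batch effects, imputation
panels. Tests passing on these synthetics therefore demonstrate the
*machinery* — calibration of the permutation test, convergence of the
sampler, correctness of the bookkeeping — not robustness to real-data
artefacts.

## Design choices that were genuinely open

* **Effect-size prior.** The variance-explained parameterisation
  $\sigma_a^2 = h/((1-h)\sum s_j^2)$ is one of several ways to give $h$ its
  meaning; it was chosen because it makes the prior self-calibrating across
  regions with different allele-frequency spectra.
* **Sparsity prior scaling.** "1–5 relevant SNPs per region" is applied to
  a region's actual SNP count. For very small test regions this makes the
  prior comparatively dense (1–5 expected out of, say, 20), which raises
  the null level of sum-PIP; the permutation test absorbs this because the
  null statistics shift identically.
* **Trailing window rule.** End-anchoring the final window (rather than
  allowing a short trailing window) was chosen so all full-chromosome
  windows have equal size; the alternative would make the sparsity prior's
  meaning drift at chromosome ends.
* **Early-stop criterion.** The unreachable-significance bound was chosen
  over "running p exceeds the threshold" precisely because it is
  decision-equivalent to the full run; the looser phrasing is not.
* **Tie and degenerate-input rules.** Allele-frequency ties at 0.5 keep
  the input orientation (making orientation idempotent); exceedance ties
  count against significance (conservative); subjects with missing
  phenotype are dropped with a logged count; constant phenotypes, empty
  regions and fully-missing SNP columns are rejected with diagnostics.
* **Proposal mixture.** The three model moves are drawn uniformly; the
  historical samplers this follows do not document their mixture weights,
  so uniformity is declared rather than inferred.

## Problem sizes used by the shipped experiments

The package's own acceptance experiments run at sizes a laptop CPU handles
in minutes, chosen once: convergence is demonstrated on a 200-SNP region
with 500 balanced subjects and $10^5$-sweep chains; sampler-vs-enumeration
agreement on 8-SNP regions with model size capped at 2 and a 3-point
$h$ grid; permutation calibration on 200 null regions of 10 SNPs and 60
subjects at 200 permutations each; recovery/replication on an 8-region
genome (two chromosomes of 125 SNPs in short tight LD blocks) with three
causal variants in distinct blocks of one window (aggregate $h = 0.15$)
in cohorts of ~560 balanced subjects, with the $h$ prior box widened to
$[10^{-4}, 0.2]$ so it covers the planted signal.
At these scales the full-protocol settings ($10^6$ sweeps, $10^5$
permutations, 1000-SNP windows) are configuration changes, not code
changes.

## Known limitations

* PIPs are inclusion frequencies; at full scale ($10^6$ sweeps) their
  Monte-Carlo error is small, but short test-scale chains carry visible
  noise, which is why region statistics (sums/means of many PIPs) are the
  quantities the protocol tests.
* The permutation engine refits the sampler for every permutation; the
  honest cost of the protocol is high and the package makes no
  approximation to hide it. Budgets and early stopping are the only
  levers.
* The probit latent-variable sampler mixes slowly if a region contains
  extremely rare variants (near-monomorphic columns); such columns are
  excluded from the model rather than regularised.
* Cross-dataset LD needs a reference panel containing both SNP sets; with
  synthetic data this is free, with real data it is an analysis decision.
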