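# regionbvs

Region-based Bayesian variable selection for case-control genome-wide
association studies.

Single-SNP GWAS tests one variant at a time and can miss association
signals carried jointly by several nearby, correlated variants. `regionbvs`
implements the region-based alternative: each chromosome is cut into
overlapping windows of a fixed number of SNPs (1000 SNPs with 500-SNP
overlap at full scale), and within every window a sparse spike-and-slab
probit regression is fitted by MCMC,

&nbsp;&nbsp;&nbsp;&nbsp;*z<sub>i</sub>* = *μ* + Σ<sub>j∈γ</sub> *β<sub>j</sub> x<sub>ij</sub>* + *ε<sub>i</sub>*, &nbsp; *ε<sub>i</sub>* ~ N(0, 1), &nbsp; *y<sub>i</sub>* = **1**(*z<sub>i</sub>* > 0),

with *β<sub>j</sub>* ~ N(0, σ<sub>a</sub>²), σ<sub>a</sub>² =
*h* / ((1 − *h*) Σ<sub>j∈γ</sub> *s<sub>j</sub>*²), a uniform prior on *h*
(the proportion of liability variance explained, 0.01–1% by default), a
log-uniform prior on the per-SNP inclusion probability π implying 1–5
relevant SNPs per region, and a hard cap of 5 SNPs in the model at once.
Each SNP's **posterior inclusion probability** (PIP) is its MCMC inclusion
frequency; the region statistic is the **sum of PIPs** (discovery) or the
**mean PIP** (validation, where platform differences change the marker
count). Significance is assessed by phenotype permutation with Bonferroni
correction (α = 0.1 over regions in discovery, α = 0.05 over candidates in
validation) and an early-stopping rule that provably never changes a
significance decision. A cross-dataset consensus analysis pairs the
top-PIP SNPs of two scans within 100 kb and checks whether the pairs are
in linkage disequilibrium (squared dosage correlation).

The package also ships a synthetic genotype/phenotype generator
(LD-block Gaussian-copula haplotypes, liability-threshold phenotypes,
platform subsetting, missingness) so that the entire pipeline is testable
without controlled-access genotype data, plus readers for BIMBAM-style
mean-genotype text files and PLINK text (.ped/.map) with the standard
preprocessing: minor-allele dosage coding and per-SNP mean imputation.

## Worked example

Simulate a 60-SNP region (one tight LD block, one loose block) for 400
subjects with two causal variants, fit the region model with two chains,
then scan the genome with a permutation test:

```r
library(regionbvs)

layout <- list("1" = list(block_spec(30, rho = 0.8, maf_range = c(0.1, 0.5)),
                          block_spec(30, rho = 0.2, maf_range = c(0.1, 0.5))))
G   <- simulate_genotypes(400, layout, seed = 1)
sim <- simulate_phenotype(G, n_causal = 2, per_variant_h = 0.1,
                          prevalence = 0.5, seed = 2, causal_indices = c(5L, 40L))

fit <- run_bvs(G, sim$phenotype,
               priors = bvs_priors(h_max = 0.3),
               config = bvs_config(n_iter = 20000, n_chains = 2, seed = 3))
summary(fit)
```

```
Region of 60 SNPs, 400 subjects (2 chain(s))
sum of PIPs 3.069, mean PIP 0.05114
Gelman-Rubin PSRF: h 0.9997, log-joint 0.9997 (bound 1.04)
Top SNPs by posterior inclusion probability:
   snp_id chrom    pos     pip neg_log10_one_minus_pip
 chr1_s40     1 295000 1.00000                 6.00000
  chr1_s5     1 120000 0.85678                 0.84400
 chr1_s12     1 155000 0.09862                 0.04509
  chr1_s6     1 125000 0.09422                 0.04298
  chr1_s4     1 115000 0.07041                 0.03171
 ...
```

The causal SNP in the loose block (`chr1_s40`) is pinned with PIP 1; the
causal SNP inside the ρ = 0.8 block (`chr1_s5`) keeps PIP 0.86 with the
remainder of its evidence spread over its correlated neighbours
(`chr1_s12`, `chr1_s6`, `chr1_s4`) — exactly the signal-spreading behaviour
that motivates summing PIPs over a region. Both chains agree
(Gelman–Rubin < 1.04). The last column is the Manhattan-plot scale
−log10(1 − PIP), clipped at PIP = 1 − 10⁻⁶.

```r
regions <- partition_genome(G, window = 30, step = 15)
scan <- genomewide_scan(G, regions, sim$phenotype, bvs_priors(h_max = 0.3),
                        bvs_config(n_iter = 2000, seed = 4),
                        alpha = 0.1, B_target = 50, batch = 10, master_seed = 5)
scan
```

```
<bvs_scan> 3 region(s); Bonferroni-adjusted alpha = 0.0333; 2 significant
  chrom rank_on_chrom start_pos end_pos rank  sum_pip p_text significant
1     1             2    175000  320000    1 3.035625  <0.02        TRUE
2     1             1    100000  245000    2 2.320625   0.02        TRUE
3     1             3    250000  395000    3 1.915000    0.3   FALSE
```

Regions are ranked by empirical p-value (`<0.02` means no permuted
statistic reached the observed one within the budget); the two overlapping
windows containing the causal SNPs are significant at the
Bonferroni-adjusted level, the null window is not. `validate_regions()`
re-tests candidates on an independent cohort via mean-PIP permutations,
`overlap_consensus()` runs the cross-dataset LD consensus, and
`run_pipeline(pipeline_config(...))` drives the whole
simulate/read → partition → scan → validate → consensus workflow from one
seeded configuration, writing TSV tables, Manhattan/region plots and a
run log whose numbers reproduce bit-identically for a given master seed.

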