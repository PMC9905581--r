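# wkgs — weighted-kernel genomic selection across environments

`wkgs` is an R package for genomic prediction of quantitative traits
across multiple environments, aimed at breeding programs where
genotype-by-environment (G×E) interaction and genetically heterogeneous
material (doubled-haploid lines replicated across years, or half-sib
families split across sites) undermine single-environment genomic
selection.

Its core idea: instead of a Gaussian kernel that treats every SNP as an
equal contributor to genomic similarity, build a **weighted kernel** whose
per-marker weights encode the trait's genetic architecture —

```
w_l = ( c1 * Beta(MAF_l; alpha, beta)  +  1/(0.1 + p1_l)  +  1/(0.1 + p2_l) )^2
```

where `p1_l`, `p2_l` are FDR-adjusted p-values of the marker main effect
and of the marker×environment interaction from a G×E-aware genome scan,
and the Beta density (`alpha = 1`) up-weights rare variants that
association scans are underpowered to detect. The scaling constant

```
c1 = max( 1/(0.1 + p1), 1/(0.1 + p2) ) / Beta(min(MAF); alpha, beta)
```

balances the two sources; in the limit of a zero minimum adjusted p-value
and zero minimum MAF, `c1 -> 10/beta` (0.83, 0.40, 0.20, 0.10, 0.05 for
`beta` = 12, 25, 50, 100, 200). The weighted (or Gaussian,
`K = exp(-h d^2/s)`) kernel then enters Bayesian kernel mixed models:

* **SE model** per environment `j`:
  `y_j = 1 mu_j + g_j + b_j + e_j`, `g_j ~ N(0, sigma2_g_j K_j)`, with a
  background genetic effect `b_j ~ N(0, sigma2_b_j B_j)`;
* **ME model** over stacked environments, with genetic covariance blocks
  `cov(g_j, g_k) = sigma_g_jk K_jk` — an environment-level genetic
  covariance matrix expanded over within- and cross-environment kernel
  blocks — fitted by Gibbs sampling in a fast Kronecker regime (identical
  lines everywhere) or a general regime (disjoint individuals per
  environment, Metropolis-within-Gibbs for the environment covariance,
  compiled inner loop).

A CV2-style cross-validation harness (70/30 partitions, per-partition
recomputation of MAF/scan/weights, `beta` grid selection on training
data, PCOR/MSE per environment) compares the model variants `SE_GK`,
`ME_GK`, `ME_WK_MAF`, `ME_WK_Pvalue`, `ME_WK_MAF_Pvalue`, and a
synthetic-data generator reproduces the relevant population structures so
everything is testable without external data.

## Worked example

Simulate a doubled-haploid population (120 lines, 2 environments, 500
markers, 20 QTL, heritability 0.5, cross-environment genetic correlation
0.8), scan it, build the weighted kernel, and fit the multi-environment
model:

```r
library(wkgs)

cfg   <- sim_config("dh_shared_lines", n = 120, m = 2, p = 500,
                    n_qtl = 20, h2 = 0.5, genetic_cor = 0.8, seed = 42)
panel <- simulate_genotypes(cfg)
sim   <- simulate_phenotypes(panel, cfg)

scan <- run_gwas(panel, sim$phenos, "trait1")
scan
#> G x E association scan: 500 markers, trait trait1
#>   markers with adjusted main-effect p < 0.05: 4
#>   markers with adjusted interaction p < 0.05: 0

w <- weights_maf_pvalue(compute_maf(panel), scan$p_main_adj,
                        scan$p_gxe_adj, alpha = 1, beta = 12)
w
#> Marker weights (MAF_Pvalue), p = 500
#>   alpha = 1, beta = 12, c1 = 0.8333
#>   weight range [3.324, 159.7]

kset <- assemble_kernel_set(panel, sim$phenos, weights = w, h = 1)
fit  <- fit_me(sim$phenos, kset, regime = "kronecker",
               iters = 5000, burnin = 2500, seed = 1)
fit
#> Multi-environment Bayesian kernel fit (kronecker regime)
#>   n = 240 records, 2 environments; 5000 iterations (burn-in 2500, thin 10)
#>   posterior mean environment genetic covariance:
#>         E1      E2
#> E1  9.6473 10.1637
#> E2 10.1637 15.5655
#>   posterior mean genetic correlations:
#>       E1    E2
#> E1 1.000 0.829
#> E2 0.829 1.000
#>   h2 per environment: E1=0.526, E2=0.562
```

The four significant markers are among the 20 simulated QTL; `c1` sits at
its `10/beta = 0.83` limit because the strongest association reaches an
adjusted p-value of 0; the posterior genetic correlation (0.83) and
per-environment heritabilities (0.53, 0.56) recover the simulation
targets (0.8, 0.5). Held-out records are predicted with
`predict_cv2(fit, kset, background, train_mask, test_mask)`, and

```r
report <- run_experiment(panel, sim$phenos, "trait1",
                         variants = c("SE_GK", "ME_GK", "ME_WK_MAF_Pvalue"),
                         config = run_config(reps = 10L, holdout = "cell"))
```

runs the full cross-validated comparison (PCOR and MSE per variant,
environment and replicate, plus aggregated means and standard errors).

A small command-line wrapper around the same functions lives at
`inst/cli/wkgs` with subcommands `simulate`, `gwas`, `kernel`, `fit`,
`cv`; every run directory receives a JSON manifest (config hash, input
checksums, seeds) for reproducibility.

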