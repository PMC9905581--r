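---
title: "Weighted-kernel genomic selection across environments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-kernel genomic selection across environments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkgs)
```

## The problem

Genomic selection (GS) predicts the phenotype or breeding value of
unphenotyped individuals from genome-wide markers. Two things routinely
degrade single-environment GS models in variety improvement programs:
genotype-by-environment (G×E) interaction, which makes a genotype's effect
change magnitude or sign across sites and seasons, and genetically
heterogeneous material — open-pollinated half-sib families, for instance —
where no clonal replicates exist to separate G×E from genetic variance.

`wkgs` implements a GS framework that addresses both. It couples

1. **multi-environment Bayesian kernel mixed models** that estimate
   per-environment genetic variances and cross-environment genetic
   covariances, for populations of identical lines replicated in every
   environment (doubled haploids) *or* disjoint individuals per environment
   (half-sib families spanning sites), with
2. **trait- and population-specific weighted kernels** whose per-marker
   weights combine minor allele frequency (MAF) with association signal
   from a G×E-aware genome scan, so the kernel reflects the trait's genetic
   architecture instead of uniform genomic similarity.

## Models

### Single-environment (SE) model

For environment $j$ with $n_j$ records,

$$\mathbf{y}_j = \mathbf{1}_{n_j}\mu_j + \mathbf{g}_j + \mathbf{b}_j + \mathbf{e}_j,$$

with $\mathbf{g}_j \sim N(0, \sigma^2_{g_j}\mathbf{K}_j)$ the marker-driven
genetic effect, $\mathbf{b}_j \sim N(0, \sigma^2_{b_j}\mathbf{B}_j)$ a
background genetic effect not captured by the markers, and
$\mathbf{e}_j \sim N(0, \sigma^2_{e_j}\mathbf{I})$. `fit_se()` fits this by
Gibbs sampling.

### Multi-environment (ME) model

Stacking all environments, $\mathbf{y} = \mu + \mathbf{g} + \mathbf{b} +
\mathbf{e}$, where the genetic covariance has blocks
$\mathrm{cov}(\mathbf{g}_j, \mathbf{g}_k) = \sigma_{g_{jk}}\mathbf{K}_{jk}$:
an environment-level genetic covariance matrix
$G_{\mathrm{env}} = [\sigma_{g_{jk}}]$ expanded over kernel blocks relating
the individuals of environments $j$ and $k$. The background covariance is
built the same way from $\mathbf{B}$ blocks, and residuals are independent
with per-environment variances. `fit_me()` fits this model; the
cross-environment covariances are what let a record of a line in one
environment inform its prediction in another.

### Background matrices

`build_background()` supports two modes. `identity` (no pedigree
information): $\mathbf{B} = \mathbf{I}$ and all cross-environment
background covariances are fixed at zero. `half_sib`: distinct records of
same-family individuals get the expected half-sib additive relatedness
0.25, within and across environments, and the cross-environment background
covariances are estimated. With $\mathbf{B} = \mathbf{I}$ the background
and residual variances are only weakly separated (their sum is what the
data identify); heritability estimates, which use the sum, are unaffected.

## Kernels and marker weights

The Gaussian kernel (GK) is
$K_G(x_i, x_k) = \exp(-h\, d^2_{ik}/s)$ with $d^2_{ik}$ the squared
Euclidean distance between dosage vectors and $s$ the largest observed
$d^2_{ik}$. The weighted kernel (WK) replaces the distance by
$d^{*2}_{ik} = \sum_l w_l (x_{il} - x_{kl})^2$, normalized by the maximum
$s^*$. The per-marker weight is

$$w_l = \Big(c_1\,\mathrm{Beta}(\mathrm{MAF}_l;\alpha,\beta)
  + \tfrac{1}{0.1 + p^{(1)}_l} + \tfrac{1}{0.1 + p^{(2)}_l}\Big)^2,$$

where $p^{(1)}_l, p^{(2)}_l$ are FDR-adjusted p-values of the marker main
effect and of the marker-by-environment interaction from the genome scan,
and the Beta density (with $\alpha = 1$ fixed) is large near MAF 0, so
rare variants — which association scans are underpowered to detect but
which carry disproportionately large effects — are not drowned out. The
scaling constant

$$c_1 = \frac{\max\big(\tfrac{1}{0.1+\mathbf{p}^{(1)}},
  \tfrac{1}{0.1+\mathbf{p}^{(2)}}\big)}
  {\mathrm{Beta}(\min(\mathbf{MAF});\alpha,\beta)}$$

balances the frequency term against the association terms: at the extremes
(smallest adjusted p-value and smallest MAF both 0, $\alpha = 1$),
$c_1 \to 10/\beta$, i.e. 0.83, 0.40, 0.20, 0.10, 0.05 for
$\beta \in \{12, 25, 50, 100, 200\}$. That is why $\beta$ cannot be sent to
infinity to switch the MAF term off, and why the package evaluates exactly
this grid. MAF-only ($w_l = (c_1 \mathrm{Beta}(\mathrm{MAF}_l))^2$) and
p-value-only ($w_l = (\tfrac{1}{0.1+p^{(1)}_l} + \tfrac{1}{0.1+p^{(2)}_l})^2$)
variants are provided for comparison.

**Normalizer scope.** For multi-environment kernel sets the normalizer is
the maximum (weighted) squared distance over *all* record pairs, shared by
every within- and cross-environment block. A single shared scale is the
only choice under which the assembled matrix is itself a positive
semidefinite kernel; per-block maxima would break that. A single
environment used alone (the SE model) normalizes by its own maximum.

**Bandwidth.** $h = 1$ throughout, exposed in the configuration for
completeness but not tuned; bandwidth tuning is uniform over markers and
orthogonal to what the weights contribute.

**Degenerate inputs.** A panel in which all genotype vectors coincide has
zero maximal distance; the kernel constructors raise an error rather than
silently returning an identity-like matrix, because such input almost
always indicates an upstream bug.

## The association scan

The weights need exactly two p-values per marker, for the main genotypic
effect and for the G×E interaction. `run_gwas()` fits, per marker by least
squares on the stacked records,

$$y = \mathrm{intercept} + \mathrm{environment} + \mathrm{marker}
  + \mathrm{marker}\times\mathrm{environment} + \varepsilon .$$

The interaction columns use sum-to-zero environment contrasts, so the
marker main-effect coefficient estimates the slope *averaged over
environments* — invariant to environment relabeling, and correctly near
zero for a pure crossover interaction (which the interaction F-test, of
all $m-1$ interaction terms against the nested model, then flags). With
treatment contrasts the "main effect" would instead be the slope in an
arbitrary reference environment. Both p-value vectors are
Benjamini–Hochberg adjusted before they enter the weights; BH is
parameter-free and deterministic, and because adjusted p-values enter the
weights continuously, the nominal 0.05 level is metadata rather than a
threshold anywhere in the computation.

Two conventions keep the weight vector aligned with the kernel's marker
set: a constant marker gets both p-values set to 1 (weight floor) instead
of being dropped, and aliased interaction columns (a marker segregating in
only one environment) are dropped with a flag. The scan deliberately does
not correct for relatedness: the downstream kernel model absorbs it, and a
kinship-corrected scan inside every cross-validation partition would be
prohibitively slow. This is a documented divergence risk — in strongly
structured populations the raw scan's p-values are anti-conservative, and
the weights inherit that.

## Samplers

The exact sampler distributions are the package's own choices, selected to
be weakly informative, proper, and conjugate where conjugacy exists:

* scalar variances ($\sigma^2_{g_j}$ in the SE model, $\sigma^2_{b_j}$,
  $\sigma^2_{e_j}$): scaled-inverse-$\chi^2$ with df 5 and scale half the
  (per-environment) phenotypic variance;
* environment genetic covariance $G_{\mathrm{env}}$, Kronecker regime:
  inverse-Wishart with df $m + 2$ and scale
  $\mathrm{diag}(\mathrm{var}(y_j)/2)$;
* $G_{\mathrm{env}}$, general regime: the same scaled-inverse-$\chi^2$ on
  the variances and uniform$(-1, 1)$ on the correlations;
* environment means: flat.

**Kronecker regime** (`fit_me(..., regime = "kronecker")`): when the same
individuals appear in every environment, the genetic covariance is
$G_{\mathrm{env}} \otimes \mathbf{K}$ and the model is a multi-trait kernel
model. Sampling runs in the eigenbasis of $\mathbf{K}$, where the rows of
the transformed genetic-effect matrix decouple, so one sweep costs
$O(n^2)$ and $G_{\mathrm{env}}$ has a conjugate inverse-Wishart update.
Background cross-environment covariances are fixed at zero in this regime
(the identity-background convention); the background matrix, if not the
identity, must be shared across environments.

**General regime** (`regime = "general"`): with disjoint individuals the
genetic covariance is the Hadamard product
$\Sigma_g[i,k] = G_{\mathrm{env}}[\mathrm{env}(i),\mathrm{env}(k)]\cdot
\mathbf{K}[i,k]$, which breaks conjugacy. $G_{\mathrm{env}}$ is updated by
a joint random-walk Metropolis step on log-variances and Fisher-z
correlations; non-positive-definite proposals are rejected outright and
never stored. The proposal scale adapts during burn-in toward a 20–45%
acceptance rate (multiplicative updates on 50-iteration windows) and is
frozen afterwards to preserve detailed balance. Latent effects are drawn
exactly by the residual-decomposition device
$g = u + \Sigma_g V^{-1}(r - u - \delta)$ with $u \sim N(0, \Sigma_g)$,
$\delta \sim N(0, D_e)$, $V = \Sigma_g + D_e$, which costs one Cholesky
factorization; a second factorization serves the Metropolis proposal. With
a half-sib background the background covariance parameters get the same
Metropolis treatment, but the family-block structure keeps those
factorizations small. The inner loop is compiled (RcppArmadillo) and works
on preallocated buffers.

**Numerical safeguards.** Kernel and covariance diagonals get a $10^{-8}$
relative jitter before factorization; eigendecompositions clamp
eigenvalues below $10^{-10}$ of the maximum (rank-deficient kernels are
routine); a clearly indefinite kernel is an error; a non-finite draw
aborts with the iteration index; a singular training covariance in
prediction is retried once with a $10^{-8}$ ridge.

**Iterations.** Defaults are 12000/6000 (SE), 20000/10000 (ME Kronecker)
and 100000/50000 (ME general) iterations/burn-in with thinning 10,
reflecting the very different mixing speeds of the conjugate and
Metropolis-within-Gibbs updates. Chains are bit-reproducible given a seed.
`summary()` reports effective sample sizes (via `coda` when installed) and
`plot()` draws trace plots.

**Prediction.** `predict_cv2()` computes, for each stored (thinned)
posterior draw, the conditional mean of the held-out records given the
training phenotypes under that draw's parameters, and averages the
conditional means over draws. Averaging over draws rather than plugging in
posterior means is closer to the Bayesian predictive; the two differ only
at Monte-Carlo scale, which the reduction-to-SE tests exploit.

## Cross-validation harness

`run_experiment()` evaluates model variants (`SE_GK`, `ME_GK`,
`ME_WK_MAF`, `ME_WK_Pvalue`, `ME_WK_MAF_Pvalue`) over repeated random
70/30 training/testing partitions (50 by default), scoring Pearson
correlation (PCOR) and mean squared error (MSE) per environment.

* **No information leak:** MAF, the genome scan, the weights, and the
  $\beta$ choice are recomputed inside every partition from training
  records only. Genotypes of test individuals participate in the kernel
  (as in practice: candidates are genotyped, not phenotyped).
* **Holdout modes.** `line` holds out whole individuals from every
  environment simultaneously (the $n_{70}\times m$ layout); `cell` holds
  out (individual, environment) cells within each environment, the CV2
  scenario in which individuals are observed in some environments and
  predicted in others. Both are first-class. The multi-environment model's
  advantage over per-environment fits is structural in cell mode (the
  model interpolates a line's own record from correlated environments) and
  much smaller in line mode; comparisons in the package's tests use cell
  mode for exactly that reason.
* **$\beta$ selection.** The candidate grid is $\{12, 25, 50, 100, 200\}$.
  Where a grid is evaluated, the package uses inner 80/20 splits of the
  training records (5 repeats), picks the $\beta$ with the highest mean
  inner-fold PCOR, and breaks ties toward the smaller value (stronger
  rare-variant up-weighting via $c_1 \approx 10/\beta$). The inner
  protocol is the package's own fixed choice.
* **Failed replicates** are recorded and excluded with a warning — never
  silently, since silent exclusion biases averages invisibly.

## The synthetic-data generator

No real genotype/phenotype data ship with the package; `simulate_genotypes()`
and `simulate_phenotypes()` generate datasets with the statistical
structure the models assume.

* **MAF spectra** are two-component mixtures: a low-frequency Beta
  component and a common component concentrated near 0.5, mixed to hit a
  target fraction of markers below MAF 0.2 (defaults 0.64 for the
  doubled-haploid-like design, 0.88 for the half-sib-like design, spanning
  the bimodal and rare-allele-heavy spectra typical of the respective
  genotyping-by-sequencing panels). The exact component shapes are the
  package's own choice; only the below-0.2 mass is calibrated.
* **Doubled-haploid design**: fully homozygous lines (dosages 0/2), one
  genotype row per line referenced by every environment.
* **Half-sib design**: a common-parent gamete model — offspring of a
  family share a dam whose gamete is drawn per offspring, the paternal
  gamete comes from the population — giving expected within-family
  relatedness 0.25 with realistic variation around it, rather than
  imposing 0.25 exactly through a target relationship matrix. Families
  span environments; individuals are disjoint per environment.
* **Phenotypes**: per-environment QTL effect vectors with a configurable
  cross-environment correlation (shared-plus-specific decomposition via
  the Cholesky factor of the correlation matrix), optional inverse
  MAF–effect-size coupling (`effect_maf_exponent = -1` gives every QTL an
  equal expected variance contribution, i.e. rare variants get large
  effects), residual variances set from the realized genetic variance to
  hit target heritabilities, and an optional family-level background
  effect.

What the simulator does **not** emulate: linkage disequilibrium (markers
are independent), selection and drift, genotyping error, and missingness
mechanisms beyond missing-completely-at-random. Tests passing on this
generator therefore demonstrate correctness of the machinery and
qualitative behaviour of the models — not performance on real LD-structured
panels, where tagging of causal variants and the scan's behaviour under LD
matter.

## Preprocessing conventions

Markers with a missing fraction *strictly above* 0.5 are removed (a marker
at exactly the threshold is kept, matching the strict reading of a ">50%
missing" rule). Remaining missing calls are imputed by the marker mean and
kept fractional — Euclidean kernel distances accept fractional dosages, and
rounding would discard information. MAF is `min(f, 1-f)` with `f` the mean
dosage over 2; within cross-validation it is recomputed from training
individuals only (`subset_individuals()` makes that cheap).

## Problem sizes in the test suite

The statistical tests run at sizes chosen to give the assertions
comfortable power while keeping the suite practical to run routinely:
null-calibration of the scan at 100 lines × 3 environments × 200 markers
over 50 replicates; parameter recovery for the general regime at 200
individuals per environment × 2 environments over 20 replicate datasets
with 10000/5000 iterations; the model-comparison experiments at 150 lines,
600–1000 markers, 10 cross-validation replicates with shortened chains.
The recovery tolerances (±0.15 on the genetic correlation, ±0.1 on
heritability, averaged over replicates) reflect Monte-Carlo and sampling
error at those sizes, not the models' asymptotic behaviour.

## Known limitations

* The genome scan ignores population structure; weights inherit any
  resulting anti-conservativeness (documented above).
* Kronecker-regime fits fix background cross-environment covariances at
  zero; use the general regime if those matter.
* Only additive (dosage-linear) kernels are provided; no dominance or
  epistasis kernels, and no kernel averaging or bandwidth estimation.
* The general-regime Metropolis step mixes slowly for $m \gtrsim 5$
  environments (a joint random walk in $m(m+1)/2$ dimensions); the
  defaults assume the 2–3 environment setting the framework targets.
* `estimate_h2()` follows the GBLUP convention only if the fit used the
  additive linear kernel (`linear_kernel()` / `method = "linear"`); with a
  Gaussian kernel the ratio is a kernel-variance fraction, not a
  narrow-sense heritability.
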