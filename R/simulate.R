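#' Configuration for synthetic genotype/phenotype data
#'
#' Defines the population structure the simulator emulates. Two designs
#' are supported: `dh_shared_lines` (fully homozygous doubled-haploid
#' lines, each phenotyped in every environment, with a bimodal allele
#' frequency spectrum: heavy low-frequency mass plus a mode near 0.4-0.5,
#' about 64\% of markers below MAF 0.2 by default) and
#' `half_sib_disjoint` (open-pollinated half-sib families whose members
#' are split across environments, disjoint individuals per environment,
#' rare-allele-heavy spectrum, about 88\% below MAF 0.2 by default).
#'
#' @param design `"dh_shared_lines"` or `"half_sib_disjoint"`.
#' @param n individuals per environment.
#' @param m number of environments.
#' @param p number of biallelic markers (unlinked).
#' @param maf_below_02 target fraction of markers with MAF < 0.2
#'   (defaults 0.64 / 0.88 by design).
#' @param n_qtl number of causal markers.
#' @param h2 per-environment narrow-sense heritability target (scalar or
#'   length-`m`).
#' @param genetic_cor cross-environment genetic correlation: scalar
#'   (compound-symmetric) or an `m x m` positive definite correlation
#'   matrix.
#' @param n_families number of half-sib families (half-sib design).
#' @param sigma2_b family-level background variance (half-sib design;
#'   default 0).
#' @param effect_maf_exponent exponent coupling QTL effect size to allele
#'   frequency: effect standard deviations are scaled by
#'   `(2 f (1-f))^(effect_maf_exponent / 2)`; 0 (default) decouples them,
#'   -1 gives every QTL an equal expected variance contribution, i.e.
#'   rare variants get large effects.
#' @param env_means per-environment phenotype means (default
#'   `10 + 2 * (0:(m-1))`).
#' @param seed integer seed; fixing it fixes every output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(design = c("dh_shared_lines", "half_sib_disjoint"),
                       n = 200, m = 3, p = 1000,
                       maf_below_02 = NULL, n_qtl = 50, h2 = 0.5,
                       genetic_cor = 0.8, n_families = 25, sigma2_b = 0,
                       effect_maf_exponent = 0, env_means = NULL,
                       seed = 1L) {
  design <- match.arg(design)
  if (is.null(maf_below_02)) {
    maf_below_02 <- if (design == "dh_shared_lines") 0.64 else 0.88
  }
  if (length(h2) == 1L) h2 <- rep(h2, m)
  stopifnot(length(h2) == m, all(h2 > 0), all(h2 < 1), n_qtl <= p,
            n_qtl >= 1, maf_below_02 > 0, maf_below_02 < 1)
  if (is.matrix(genetic_cor)) {
    stopifnot(nrow(genetic_cor) == m, ncol(genetic_cor) == m)
    Gamma <- genetic_cor
  } else {
    Gamma <- matrix(genetic_cor, m, m)
    diag(Gamma) <- 1
  }
  if (min(eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("genetic correlation matrix must be positive definite")
  }
  if (is.null(env_means)) env_means <- 10 + 2 * (seq_len(m) - 1L)
  stopifnot(length(env_means) == m)
  structure(
    list(design = design, n = n, m = m, p = p,
         maf_below_02 = maf_below_02, n_qtl = n_qtl, h2 = h2,
         Gamma = Gamma, n_families = n_families, sigma2_b = sigma2_b,
         effect_maf_exponent = effect_maf_exponent,
         env_means = env_means, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Two-component allele-frequency spectrum: a low-frequency Beta component
# and a common component concentrated near 0.5, mixed to hit the target
# fraction of markers below MAF 0.2.
sample_maf_spectrum <- function(p, frac_below_02) {
  lo_shape <- c(0.6, 5)    # mass piled toward 0
  hi_shape <- c(9, 1.6)    # mode near 0.85 on [0,1] -> MAF near 0.42
  p_lo <- stats::pbeta(0.4, lo_shape[1], lo_shape[2])
  p_hi <- stats::pbeta(0.4, hi_shape[1], hi_shape[2])
  mix <- (frac_below_02 - p_hi) / (p_lo - p_hi)
  mix <- min(max(mix, 0), 1)
  low <- stats::runif(p) < mix
  x <- numeric(p)
  x[low] <- stats::rbeta(sum(low), lo_shape[1], lo_shape[2])
  x[!low] <- stats::rbeta(sum(!low), hi_shape[1], hi_shape[2])
  maf <- 0.5 * x
  pmin(pmax(maf, 0.005), 0.5)   # keep every marker polymorphic
}

#' Simulate a genotype panel
#'
#' `dh_shared_lines`: each line is fully homozygous (dosages 0 or 2,
#' never 1) and shared across environments (no environment labels on the
#' panel). `half_sib_disjoint`: a common-parent gamete model -- each
#' family shares a dam whose gamete is drawn per offspring, the paternal
#' gamete comes from the population -- yielding expected within-family
#' relatedness 0.25 (realized values vary around it); families span all
#' environments, individuals are disjoint per environment.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_panel()]; the realized allele frequency vector is
#'   attached as attribute `"truth_freq"`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 11L))
  p <- cfg$p
  maf <- sample_maf_spectrum(p, cfg$maf_below_02)
  if (cfg$design == "dh_shared_lines") {
    n <- cfg$n
    calls <- matrix(2 * stats::rbinom(n * p, 1L, rep(maf, each = n)), n, p)
    ids <- sprintf("L%03d", seq_len(n))
    panel <- genotype_panel(calls, individual_ids = ids,
                            marker_ids = sprintf("mk%05d", seq_len(p)))
  } else {
    m <- cfg$m
    nf <- cfg$n_families
    per_env <- rep(cfg$n %/% nf, nf)
    extra <- cfg$n - sum(per_env)
    if (extra > 0) per_env[seq_len(extra)] <- per_env[seq_len(extra)] + 1L
    total <- sum(per_env) * m
    calls <- matrix(0L, total, p)
    ids <- character(total)
    env_of <- character(total)
    family_of <- character(total)
    row <- 0L
    for (f in seq_len(nf)) {
      dam1 <- stats::rbinom(p, 1L, maf)
      dam2 <- stats::rbinom(p, 1L, maf)
      fam_id <- sprintf("F%02d", f)
      for (j in seq_len(m)) {
        for (k in seq_len(per_env[f])) {
          row <- row + 1L
          pick <- stats::runif(p) < 0.5
          mat <- ifelse(pick, dam1, dam2)
          pat <- stats::rbinom(p, 1L, maf)
          calls[row, ] <- mat + pat
          ids[row] <- sprintf("%s_E%d_%02d", fam_id, j, k)
          env_of[row] <- paste0("E", j)
          family_of[row] <- fam_id
        }
      }
    }
    panel <- genotype_panel(calls, individual_ids = ids,
                            marker_ids = sprintf("mk%05d", seq_len(p)),
                            env_of = stats::setNames(env_of, ids),
                            family_of = stats::setNames(family_of, ids))
  }
  attr(panel, "truth_freq") <- maf
  panel
}

#' Simulate multi-environment phenotypes on a panel
#'
#' Per-environment QTL effects are drawn with the configured
#' cross-environment correlation (a shared-plus-environment-specific
#' decomposition via the Cholesky factor of the correlation matrix),
#' genetic values are dosage-by-effect products, the residual variance of
#' each environment is set from the realized genetic variance to hit the
#' target heritability, and an optional family-level background effect is
#' added.
#'
#' @param panel a panel from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return List `(phenos, truth)`: a [phenotype_table()] (trait
#'   `"trait1"`) and a `sim_truth` list with QTL indices, per-environment
#'   effect vectors, true genetic values per record, realized per-
#'   environment heritability and realized effect correlations.
#' @export
simulate_phenotypes <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 12L))
  m <- cfg$m
  p <- cfg$p
  qtl <- sort(sample(p, cfg$n_qtl))
  scale_l <- rep(1, cfg$n_qtl)
  if (cfg$effect_maf_exponent != 0) {
    f <- colMeans(panel$calls[, qtl, drop = FALSE]) / 2
    f <- pmin(pmax(f, 0.005), 0.995)
    scale_l <- (2 * f * (1 - f))^(cfg$effect_maf_exponent / 2)
  }
  Z <- matrix(stats::rnorm(cfg$n_qtl * m), cfg$n_qtl, m)
  Beff <- (Z %*% chol(cfg$Gamma)) * scale_l

  if (cfg$design == "dh_shared_lines") {
    ids <- rep(panel$individual_ids, times = m)
    env <- rep(paste0("E", seq_len(m)), each = length(panel$individual_ids))
  } else {
    ids <- panel$individual_ids
    env <- unname(panel$env_of)
  }
  envs <- paste0("E", seq_len(m))
  X <- panel$calls[ids, qtl, drop = FALSE]
  g <- numeric(length(ids))
  for (j in seq_len(m)) {
    sel <- env == envs[j]
    g[sel] <- X[sel, , drop = FALSE] %*% Beff[, j]
  }
  b <- numeric(length(ids))
  if (cfg$sigma2_b > 0) {
    if (is.null(panel$family_of)) {
      stop("family background requested but the panel has no families")
    }
    fams <- unique(panel$family_of)
    for (j in seq_len(m)) {
      b_f <- stats::rnorm(length(fams), 0, sqrt(cfg$sigma2_b))
      sel <- env == envs[j]
      b[sel] <- b_f[match(panel$family_of[ids[sel]], fams)]
    }
  }
  value <- numeric(length(ids))
  h2_real <- numeric(m)
  for (j in seq_len(m)) {
    sel <- env == envs[j]
    vg <- stats::var(g[sel])
    if (vg <= 0) {
      stop("unreachable heritability: zero genetic variance in ", envs[j])
    }
    sig_e <- sqrt(vg * (1 - cfg$h2[j]) / cfg$h2[j] - cfg$sigma2_b)
    if (!is.finite(sig_e) || is.nan(sig_e)) {
      stop("unreachable heritability: background variance too large for h2 target")
    }
    e <- stats::rnorm(sum(sel), 0, sig_e)
    value[sel] <- cfg$env_means[j] + g[sel] + b[sel] + e
    h2_real[j] <- vg / stats::var(value[sel])
  }
  phenos <- phenotype_table(data.frame(
    individual_id = ids, environment = env, trait = "trait1",
    value = value, stringsAsFactors = FALSE))
  truth <- structure(
    list(qtl = qtl, effects = Beff, g = g,
         records = data.frame(individual_id = ids, environment = env,
                              stringsAsFactors = FALSE),
         h2_realized = stats::setNames(h2_real, envs),
         effect_cor = stats::cor(Beff)),
    class = "sim_truth"
  )
  list(phenos = phenos, truth = truth)
}

#' Down-sample every family to a common size per environment
#'
#' Mirrors the equalization of unbalanced family sizes: each family is
#' reduced to `per_family_n` randomly chosen individuals in every
#' environment.
#'
#' @param panel a half-sib [genotype_panel()] with `env_of` and
#'   `family_of`.
#' @param phenos matching [phenotype_table()].
#' @param per_family_n individuals to keep per family per environment.
#' @param seed integer seed.
#' @return List `(panel, phenos)` restricted to the subsample.
#' @export
subsample_families <- function(panel, phenos, per_family_n, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"),
            !is.null(panel$family_of), !is.null(panel$env_of))
  set.seed(derive_seed(seed, 13L))
  keep <- character()
  ids <- panel$individual_ids
  groups <- split(ids, list(panel$family_of[ids], panel$env_of[ids]),
                  drop = TRUE)
  for (grp in groups) {
    if (length(grp) < per_family_n) {
      stop("family with fewer than ", per_family_n,
           " individuals in an environment")
    }
    keep <- c(keep, if (length(grp) == per_family_n) grp
              else sample(grp, per_family_n))
  }
  keep <- ids[ids %in% keep]   # preserve panel order
  list(panel = subset_individuals(panel, keep),
       phenos = phenotype_table(
         phenos[phenos$individual_id %in% keep, , drop = FALSE]))
}

#' Write the simulated truth as TSV (QTL table + per-record genetic values)
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eff <- data.frame(qtl_index = truth$qtl, truth$effects)
  colnames(eff)[-1L] <- paste0("effect_E", seq_len(ncol(truth$effects)))
  utils::write.table(eff, file.path(dir, "sim_qtl_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gv <- cbind(truth$records, genetic_value = truth$g)
  utils::write.table(gv, file.path(dir, "sim_genetic_values.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
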