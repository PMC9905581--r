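test_that("doubled-haploid panels are homozygous and seed-deterministic", {
  cfg <- sim_config("dh_shared_lines", n = 50, m = 2, p = 300, seed = 81)
  panel <- simulate_genotypes(cfg)
  expect_true(all(panel$calls %in% c(0, 2)))   # no heterozygotes
  expect_null(panel$env_of)                    # lines shared across envs
  panel2 <- simulate_genotypes(cfg)
  expect_identical(panel2$calls, panel$calls)

  # shared lines: every cross-environment kernel block equals the
  # within-environment block
  sim <- simulate_phenotypes(panel, cfg)
  kset <- assemble_kernel_set(panel, sim$phenos)
  expect_equal(kernel_block(kset, "E1", "E2"), kernel_block(kset, "E1"),
               ignore_attr = TRUE)
})

test_that("allele-frequency spectra hit their low-MAF targets", {
  for (target in c(0.64, 0.88)) {
    cfg <- sim_config("dh_shared_lines", n = 30, m = 2, p = 5000,
                      maf_below_02 = target, seed = 82)
    panel <- simulate_genotypes(cfg)
    truth <- attr(panel, "truth_freq")
    expect_equal(mean(truth < 0.2), target, tolerance = 0.03)
  }
})

test_that("half-sib families are disjoint per environment and more related within", {
  cfg <- sim_config("half_sib_disjoint", n = 60, m = 2, p = 400,
                    n_families = 10, seed = 83)
  panel <- simulate_genotypes(cfg)
  expect_equal(length(panel$individual_ids), 120)
  expect_equal(unname(table(panel$env_of)), c(60L, 60L), ignore_attr = TRUE)
  # genomic relationship: within-family mean exceeds between-family mean
  G <- linear_kernel(panel$calls)$K
  fam <- panel$family_of
  same <- outer(fam, fam, "==") & !diag(TRUE, nrow(G))
  diff_fam <- !outer(fam, fam, "==")
  expect_gt(mean(G[same]), mean(G[diff_fam]) + 0.1)
})

test_that("phenotype simulation hits heritability and correlation targets", {
  cfg <- sim_config("dh_shared_lines", n = 500, m = 2, p = 400,
                    n_qtl = 100, h2 = 0.5, genetic_cor = 0.8, seed = 84)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, cfg)
  expect_true(all(abs(sim$truth$h2_realized - 0.5) < 0.1))
  expect_equal(sim$truth$effect_cor[1, 2], 0.8, tolerance = 0.12)

  # near-perfect genetic correlation: genetic values almost identical
  cfg1 <- sim_config("dh_shared_lines", n = 200, m = 2, p = 300,
                     n_qtl = 100, h2 = 0.5, genetic_cor = 0.9999,
                     seed = 85)
  p1 <- simulate_genotypes(cfg1)
  s1 <- simulate_phenotypes(p1, cfg1)
  gmat <- matrix(s1$truth$g, ncol = 2)
  expect_gt(cor(gmat[, 1], gmat[, 2]), 0.99)

  # zero genetic correlation realized near zero
  cfg0 <- sim_config("dh_shared_lines", n = 500, m = 2, p = 300,
                     n_qtl = 200, h2 = 0.5, genetic_cor = 0, seed = 86)
  p0 <- simulate_genotypes(cfg0)
  s0 <- simulate_phenotypes(p0, cfg0)
  g0 <- matrix(s0$truth$g, ncol = 2)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.15)

  # rare-variant coupling enlarges low-frequency effects
  cfgr <- sim_config("dh_shared_lines", n = 100, m = 2, p = 400,
                     n_qtl = 400, h2 = 0.5, effect_maf_exponent = -1,
                     seed = 87)
  pr <- simulate_genotypes(cfgr)
  sr <- simulate_phenotypes(pr, cfgr)
  f <- colMeans(pr$calls[, sr$truth$qtl]) / 2
  maf <- pmin(f, 1 - f)
  sizes <- abs(sr$truth$effects[, 1])
  expect_lt(cor(maf, sizes, method = "spearman"), -0.3)
})

test_that("family down-sampling equalizes sizes reproducibly", {
  cfg <- sim_config("half_sib_disjoint", n = 40, m = 2, p = 50,
                    n_families = 8, seed = 88)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, cfg)
  sub <- subsample_families(panel, sim$phenos, per_family_n = 3, seed = 4)
  tab <- table(sub$panel$family_of, sub$panel$env_of)
  expect_true(all(tab == 3))
  expect_equal(nrow(sub$phenos), length(sub$panel$individual_ids))
  sub2 <- subsample_families(panel, sim$phenos, per_family_n = 3, seed = 4)
  expect_identical(sub2$panel$individual_ids, sub$panel$individual_ids)

  # keeping the full family size is the identity
  full <- subsample_families(panel, sim$phenos, per_family_n = 5, seed = 4)
  expect_identical(full$panel$individual_ids, panel$individual_ids)

  expect_error(subsample_families(panel, sim$phenos, per_family_n = 20),
               "fewer than")
})
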