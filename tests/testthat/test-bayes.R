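test_that("background matrices encode identity and half-sib relatedness", {
  recs <- data.frame(individual_id = c("a", "b", "c"),
                     environment = "E1")
  expect_equal(build_background(recs)$full, diag(3))

  # 2 families of 2 individuals, each split across 2 environments
  recs2 <- data.frame(
    individual_id = c("f1a", "f1b", "f2a", "f2b"),
    environment = c("E1", "E2", "E1", "E2"))
  fam <- c(f1a = "F1", f1b = "F1", f2a = "F2", f2b = "F2")
  bg <- build_background(recs2, families = fam, mode = "half_sib")
  expect_equal(unname(diag(bg$full)), rep(1, 4))
  expect_equal(sum(bg$full == 0.25), 4)  # 2 unordered same-family pairs
  expect_equal(bg$full[1, 2], 0.25)      # across environments too
  expect_equal(bg$full[1, 3], 0)

  # permutation of records conjugates the matrix
  perm <- c(3, 1, 4, 2)
  bg_p <- build_background(recs2[perm, ], families = fam,
                           mode = "half_sib")
  expect_equal(bg_p$full, bg$full[perm, perm])

  expect_error(build_background(recs2, families = fam[-1],
                                mode = "half_sib"), "f1a")
})

test_that("single-environment chains are seed-reproducible and recover signal", {
  set.seed(31)
  n <- 150; p <- 120
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  K <- linear_kernel(X)$K
  beta_eff <- rnorm(p, 0, 1)
  g <- as.vector(scale(X %*% beta_eff))
  h2 <- 0.6
  y <- 3 + g + rnorm(n, 0, sqrt((1 - h2) / h2))

  f1 <- fit_se(y, K, iters = 2500, burnin = 1000, seed = 101)
  f2 <- fit_se(y, K, iters = 2500, burnin = 1000, seed = 101)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$g, f2$g)

  expect_true(all(f1$draws$sigma2_g > 0) && all(f1$draws$sigma2_e > 0))
  expect_equal(nrow(f1$draws), 150)
  h2_hat <- estimate_h2(f1)
  expect_gt(h2_hat, 0.35)
  expect_lt(h2_hat, 0.85)

  # pure-noise trait on a structured (family) kernel: genetic variance is
  # identifiable there and its heritability estimate collapses
  cfg0 <- sim_config("half_sib_disjoint", n = 300, m = 1, p = 200,
                     n_families = 25, seed = 103)
  pan0 <- simulate_genotypes(cfg0)
  K0 <- linear_kernel(pan0$calls)$K
  y0 <- rnorm(300)
  f0 <- fit_se(y0, K0, iters = 2500, burnin = 1000, seed = 102)
  expect_lt(estimate_h2(f0), 0.25)
  expect_lt(estimate_h2(f0), estimate_h2(f1))

  expect_error(fit_se(y, K - diag(0.5, n), iters = 200, burnin = 100),
               "positive semidefinite")
})

test_that("general regime with one environment agrees with the SE sampler", {
  set.seed(32)
  n <- 100; p <- 80
  X <- matrix(rbinom(n * p, 2, 0.35), n, p)
  K <- linear_kernel(X)$K
  g <- as.vector(scale(X %*% rnorm(p)))
  y <- 5 + g + rnorm(n, 0, 1)
  se <- fit_se(y, K, iters = 4000, burnin = 2000, seed = 41)

  ph <- phenotype_table(data.frame(
    individual_id = sprintf("i%03d", 1:n), environment = "E1",
    trait = "trait1", value = y))
  pan <- genotype_panel(X, individual_ids = sprintf("i%03d", 1:n))
  kset <- assemble_kernel_set(pan, ph, method = "linear")
  me <- fit_me(ph, kset, regime = "general", iters = 6000, burnin = 3000,
               seed = 42)
  # posterior means agree within Monte-Carlo error
  expect_equal(mean(me$draws$mu), mean(se$draws$mu), tolerance = 0.15)
  tot_se <- mean(se$draws$sigma2_g + se$draws$sigma2_b + se$draws$sigma2_e)
  tot_me <- mean(me$draws$G_env[, 1] + me$draws$S_b[, 1] +
                   me$draws$sigma2_e[, 1])
  expect_equal(tot_me / tot_se, 1, tolerance = 0.15)
  expect_equal(unname(estimate_h2(me)), estimate_h2(se), tolerance = 0.12)
})

test_that("kronecker and general regimes agree on shared-lines data", {
  cfg <- sim_config("dh_shared_lines", n = 120, m = 2, p = 250, n_qtl = 250,
                    h2 = 0.6, genetic_cor = 0.7, seed = 55)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, cfg)
  kset <- assemble_kernel_set(panel, sim$phenos, method = "linear")
  fk <- fit_me(sim$phenos, kset, regime = "kronecker", iters = 5000,
               burnin = 2500, seed = 61)
  fg <- fit_me(sim$phenos, kset, regime = "general", iters = 8000,
               burnin = 4000, seed = 62)
  rho_k <- mean(apply(fk$draws$G_env, 1,
                      function(s) s[2] / sqrt(s[1] * s[4])))
  rho_g <- mean(apply(fg$draws$G_env, 1,
                      function(s) s[2] / sqrt(s[1] * s[4])))
  expect_lt(abs(rho_k - rho_g), 0.15)
  expect_lt(max(abs(estimate_h2(fk) - estimate_h2(fg))), 0.12)
  # every stored environment covariance draw is positive definite
  ok <- apply(fg$draws$G_env, 1, function(s) {
    all(eigen(matrix(s, 2, 2), symmetric = TRUE,
              only.values = TRUE)$values > 0)
  })
  expect_true(all(ok))
})

test_that("conditional prediction reduces to the marginal mean when decoupled", {
  # identity kernel and diagonal environment covariance: no information
  # flows from training to disjoint test individuals
  recs <- data.frame(individual_id = sprintf("i%d", 1:8),
                     environment = rep(c("E1", "E2"), each = 4))
  train <- rep(c(TRUE, TRUE, TRUE, FALSE), 2)
  y <- c(11, 12, 13, 0, 21, 22, 23, 0)
  kset <- structure(list(
    full = diag(8), blocks = NULL, environments = c("E1", "E2"),
    records = recs, h = 1, method = "gaussian", normalizer = 1),
    class = "kernel_set")
  bg <- build_background(recs)
  fit <- make_const_me_fit(
    y[train], recs[train, ], c("E1", "E2"), mu = c(10, 20),
    G_env = diag(c(2, 3)), S_b = diag(c(0.5, 0.5)), sigma2_e = c(1, 1))
  pred <- predict_cv2(fit, kset, bg, train, !train)
  expect_equal(pred, c(10, 20))

  # interpolation limit: a test record duplicating a training record is
  # predicted at (almost) its training phenotype as sigma2_e -> 0
  recs2 <- data.frame(individual_id = c("a", "a2"), environment = "E1")
  K2 <- matrix(1, 2, 2)
  kset2 <- structure(list(full = K2, blocks = NULL, environments = "E1",
                          records = recs2, h = 1, method = "gaussian",
                          normalizer = 1), class = "kernel_set")
  bg2 <- build_background(recs2)
  fit2 <- make_const_me_fit(5, recs2[1, ], "E1", mu = 0,
                            G_env = matrix(4), S_b = matrix(1e-12),
                            sigma2_e = 1e-10)
  pred2 <- predict_cv2(fit2, kset2, bg2, c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(pred2, 5, tolerance = 1e-4)
})

test_that("heritability posterior hits the boundary cases", {
  # vanishing residual and background variance forces h2 to 1
  recs <- data.frame(individual_id = c("a", "b"), environment = "E1")
  fit <- make_const_me_fit(c(1, 2), recs, "E1", mu = 0,
                           G_env = matrix(3), S_b = matrix(1e-12),
                           sigma2_e = 1e-12)
  expect_equal(unname(estimate_h2(fit)), 1, tolerance = 1e-6)
})

test_that("posterior draws and predictions export to tidy TSV", {
  set.seed(91)
  n <- 40
  X <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  y <- rnorm(n)
  fit <- fit_se(y, linear_kernel(X)$K, iters = 400, burnin = 200, seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  write_draws_tsv(fit, tmp)
  long <- read.delim(tmp)
  expect_setequal(unique(long$parameter),
                  c("mu", "sigma2_g", "sigma2_b", "sigma2_e"))
  expect_equal(nrow(long), 4 * nrow(fit$draws))
  sm <- summary(fit)
  expect_true(all(c("ess", "rhat") %in% colnames(sm)))
  expect_true(all(sm$rhat < 1.5, na.rm = TRUE))

  tmp2 <- tempfile(fileext = ".tsv")
  recs <- data.frame(individual_id = c("a", "b"), environment = "E1")
  write_predictions_tsv(recs, c(1, 2), c(1.1, 1.9), tmp2)
  back <- read.delim(tmp2)
  expect_equal(back$predicted, c(1.1, 1.9))
})
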