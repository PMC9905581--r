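test_that("partitions respect the training fraction, mode and seed", {
  pan <- make_test_panel(n = 20, p = 5, seed = 71)
  ph <- make_test_phenos(pan, m = 3)
  parts <- make_partitions(ph, n_reps = 4, train_frac = 0.7, mode = "line",
                           seed = 5)
  for (p1 in parts) {
    expect_false(any(p1$train & p1$test))
    expect_true(all(p1$train | p1$test))
    # 14 of 20 lines in train, in every environment
    for (e in paste0("E", 1:3)) {
      sel <- ph$environment == e
      expect_equal(sum(p1$train[sel]), 14)
    }
    # line mode: the same ids are held out everywhere
    held <- split(ph$individual_id[p1$test], ph$environment[p1$test])
    expect_true(all(vapply(held, setequal, logical(1), y = held[[1]])))
  }
  expect_identical(make_partitions(ph, 4, 0.7, "line", seed = 5), parts)

  # cell mode holds out cells independently per environment
  pc <- make_partitions(ph, 2, 0.7, mode = "cell", seed = 9)[[1]]
  held <- split(ph$individual_id[pc$test], ph$environment[pc$test])
  expect_false(all(vapply(held, setequal, logical(1), y = held[[1]])))

  # each line lands in the test set a binomially plausible number of times
  many <- make_partitions(ph, 50, 0.7, "line", seed = 11)
  counts <- rowSums(sapply(many, function(p1) {
    tapply(p1$test, ph$individual_id, any)
  }))
  expect_true(all(counts >= qbinom(0.001, 50, 0.3) &
                    counts <= qbinom(0.999, 50, 0.3)))

  expect_error(make_partitions(ph[ph$individual_id %in%
                                    sprintf("i%02d", 1:6), ], 1, 0.7),
               "fewer than 5")
})

test_that("accuracy metrics match hand oracles", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pcor(x, x), 1)
  expect_equal(pcor(x, -x), -1)
  y <- c(2, 1, 4, 3, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pcor(x, y), hand)
  expect_warning(p0 <- pcor(x, rep(1, 5)), "zero variance")
  expect_true(is.na(p0))

  expect_equal(mse(x, x), 0)
  expect_equal(mse(x, x + 2), 4)
  set.seed(72)
  a <- rnorm(20); b <- rnorm(20)
  acc <- 0
  for (i in 1:20) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse(a, b), acc / 20)
})

test_that("beta selection handles degenerate grids without inner evaluation", {
  pan <- make_test_panel(n = 10, p = 5, seed = 73)
  ph <- make_test_phenos(pan, m = 2)
  sel <- select_beta(pan, ph, beta_grid = 25)
  expect_equal(sel$beta, 25)
  expect_null(sel$inner)
  # the p-value scheme has no beta dependence: grid head returned directly
  sel2 <- select_beta(pan, ph, beta_grid = c(50, 12), scheme = "Pvalue")
  expect_equal(sel2$beta, 12)
})

test_that("the experiment harness reports the requested variants", {
  cfg <- sim_config("dh_shared_lines", n = 40, m = 2, p = 80, n_qtl = 80,
                    h2 = 0.6, genetic_cor = 0.8, seed = 74)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, cfg)
  conf <- run_config(reps = 2L, beta_grid = 12,
                     se_iters = 600L, se_burnin = 300L,
                     me_iters = 600L, me_burnin = 300L, seed = 3L)
  rep1 <- run_experiment(panel, sim$phenos, "trait1",
                         variants = "ME_GK", config = conf)
  expect_s3_class(rep1, "cv_report")
  expect_equal(unique(rep1$results$variant), "ME_GK")
  expect_equal(sort(unique(rep1$results$environment)), c("E1", "E2"))
  expect_equal(max(rep1$results$replicate), 2)
  expect_true(all(rep1$results$pcor >= -1 & rep1$results$pcor <= 1))
  expect_true(all(rep1$results$mse >= 0))
  expect_true(all(c("pcor", "mse", "pcor_se", "mse_se") %in%
                    colnames(rep1$summary)))

  expect_error(run_experiment(panel, sim$phenos, "trait1",
                              variants = "NOPE", config = conf),
               "unknown variant")
})
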