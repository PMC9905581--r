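test_that("beta density matches closed forms and normalizes", {
  expect_equal(beta_density(0, 1, 12), 12)
  expect_equal(beta_density(0.5, 1, 1), 1)
  expect_equal(beta_density(0.1, 1, 25), 25 * 0.9^24)
  q <- integrate(beta_density, 0, 1, alpha = 1, beta = 25)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(beta_density(1.2, 1, 25), "\\[0, 1\\]")
})

test_that("weight-scaling constant follows its algebraic identity and limits", {
  # hand evaluation: all p-values 1, min MAF 0.5, alpha = beta = 1
  expect_equal(compute_c1(rep(1, 4), rep(1, 4), c(0.5, 0.5, 0.5, 0.5),
                          alpha = 1, beta = 1), 1 / 1.1)
  # identity: c1 * Beta(min MAF) equals the max inverse shifted p-value
  set.seed(2)
  for (r in 1:20) {
    p1 <- runif(30); p2 <- runif(30); maf <- runif(30, 0, 0.5)
    beta <- sample(c(12, 25, 50, 100, 200), 1)
    c1 <- compute_c1(p1, p2, maf, alpha = 1, beta = beta)
    expect_equal(c1 * beta_density(min(maf), 1, beta),
                 max(1 / (0.1 + p1), 1 / (0.1 + p2)))
  }
  # limit: min p -> 0 and min MAF -> 0 with alpha = 1 gives 10 / beta
  for (beta in c(12, 25, 50, 100, 200)) {
    expect_equal(compute_c1(c(0, 0.5), c(0.3, 1), c(0, 0.4), 1, beta),
                 10 / beta)
  }
  # Beta density zero at min MAF (alpha > 1, MAF 0) is an error
  expect_error(compute_c1(c(0, 1), c(1, 1), c(0, 0.2), alpha = 2, beta = 5),
               "zero")
})

test_that("marker weight schemes match algebraic oracles", {
  # a marker attaining both minima: c1 * Beta(minMAF) = 10 by construction
  maf <- c(0, 0.1, 0.4); p1 <- c(0, 0.5, 1); p2 <- c(0, 0.2, 1)
  w <- weights_maf_pvalue(maf, p1, p2, alpha = 1, beta = 25)
  expect_equal(w$w[1], (10 + 10 + 10)^2)
  expect_identical(w$scheme, "MAF_Pvalue")

  # vanishing Beta term leaves only the p-value terms
  w2 <- weights_maf_pvalue(c(0, 0.5), c(0, 1), c(0, 1), 1, 200)
  expect_equal(w2$w[2], (1 / 1.1 + 1 / 1.1)^2, tolerance = 1e-6)

  # identical inputs -> equal weights
  w3 <- weights_maf_pvalue(rep(0.2, 5), rep(0.3, 5), rep(0.6, 5), 1, 12)
  expect_true(all(w3$w == w3$w[1]))

  # MAF-only scheme: marker at the minima gets exactly 10^2
  wm <- weights_maf(maf, p1, p2, alpha = 1, beta = 25)
  expect_equal(wm$w[1], 100)
  # beta density at 0.5 is tiny for beta = 25
  expect_equal(wm$w[3] / wm$w[1], (beta_density(0.4, 1, 25) / 25)^2)

  # increasing beta shrinks the relative weight of a common marker
  ratio <- sapply(c(12, 50, 200), function(b) {
    ww <- weights_maf(c(0, 0.3), c(0, 1), c(0, 1), 1, b)
    ww$w[2] / ww$w[1]
  })
  expect_true(all(diff(ratio) < 0))

  # p-value-only scheme: plug-in values and loop oracle
  expect_equal(weights_pvalue(0, 0)$w, 400)
  expect_equal(weights_pvalue(1, 1)$w, (2 / 1.1)^2)
  set.seed(4)
  p1 <- runif(50); p2 <- runif(50)
  wp <- weights_pvalue(p1, p2)$w
  for (l in seq_len(50)) {
    expect_equal(wp[l], (1 / (0.1 + p1[l]) + 1 / (0.1 + p2[l]))^2)
  }
})

test_that("weights never decrease when adjusted p-values decrease", {
  set.seed(6)
  maf <- runif(20, 0, 0.5); p1 <- runif(20); p2 <- runif(20)
  for (scheme in c("Pvalue", "MAF_Pvalue")) {
    w0 <- if (scheme == "Pvalue") weights_pvalue(p1, p2)$w
          else weights_maf_pvalue(maf, p1, p2, 1, 25)$w
    l <- sample(20, 1)
    p1b <- p1; p1b[l] <- p1[l] / 2
    wb <- if (scheme == "Pvalue") weights_pvalue(p1b, p2)$w
          else weights_maf_pvalue(maf, p1b, p2, 1, 25)$w
    expect_gte(wb[l], w0[l])
  }
})

test_that("Gaussian and weighted kernel blocks match loop oracles", {
  set.seed(8)
  X <- matrix(sample(0:2, 5 * 10, replace = TRUE), 5, 10)
  gk <- gaussian_kernel(X, X, h = 1)
  d2 <- loop_sqdist(X, X)
  expect_equal(gk$normalizer, max(d2))
  expect_equal(gk$K, exp(-d2 / max(d2)))
  expect_equal(diag(gk$K), rep(1, 5))
  # the pair attaining the maximum distance maps to exp(-1)
  expect_equal(min(gk$K), exp(-1))

  w <- runif(10, 0.1, 5)
  wk <- weighted_kernel(X, X, weights = w, h = 1)
  d2w <- loop_sqdist(X, X, w)
  expect_equal(wk$K, exp(-d2w / max(d2w)))

  # uniform weights collapse to the Gaussian kernel exactly
  wk_u <- weighted_kernel(X, X, weights = rep(3.7, 10), h = 1)
  expect_equal(wk_u$K, gk$K, tolerance = 1e-14)

  # full weight on one marker: equal genotypes there give kernel 1
  w1 <- c(1, rep(0, 9))
  Xa <- X; Xa[2, 1] <- Xa[1, 1]
  wk1 <- weighted_kernel(Xa, Xa, weights = w1, h = 1)
  expect_equal(wk1$K[1, 2], 1)

  expect_error(weighted_kernel(X, X, weights = c(-1, w[-1])), "negative")
  same <- matrix(1, 4, 6)
  expect_error(gaussian_kernel(same, same), "degenerate")
})

test_that("linear kernel matches the VanRaden cross-product oracle", {
  set.seed(12)
  X <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40)
  lk <- linear_kernel(X)
  f <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * f)
  expect_equal(lk$K, tcrossprod(Z) / (2 * sum(f * (1 - f))))
  expect_true(isSymmetric(lk$K))
})

test_that("assembled kernel sets share one normalizer and stay PSD", {
  pan <- make_test_panel(n = 10, p = 25, seed = 14)
  ph <- make_test_phenos(pan, m = 2)
  kset <- assemble_kernel_set(pan, ph)
  # shared-lines design: every block equals the within-environment block
  expect_equal(kernel_block(kset, "E1", "E2"), kernel_block(kset, "E1"),
               ignore_attr = TRUE)
  expect_equal(kernel_block(kset, "E2", "E2"), kernel_block(kset, "E1"),
               ignore_attr = TRUE)
  expect_equal(unname(diag(kset$full)), rep(1, 20))
  expect_equal(kset$full, t(kset$full))
  ev <- eigen(kset$full, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)

  # disjoint design: 2 environments of 3 and 4 records
  pan2 <- make_test_panel(n = 7, p = 25, seed = 15)
  recs <- data.frame(individual_id = pan2$individual_ids,
                     environment = rep(c("E1", "E2"), c(3, 4)))
  k2 <- assemble_kernel_set(pan2, recs)
  expect_equal(dim(k2$full), c(7, 7))
  expect_equal(dim(kernel_block(k2, "E1", "E2")), c(3, 4))
  expect_equal(kernel_block(k2, "E2", "E1"),
               t(kernel_block(k2, "E1", "E2")))

  # permuting record order permutes the kernel consistently
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  k3 <- assemble_kernel_set(pan2, recs[perm, ])
  expect_equal(k3$full, k2$full[perm, perm], ignore_attr = TRUE)

  # a record without genotype is named in the error
  recs_bad <- rbind(recs, data.frame(individual_id = "ghost",
                                     environment = "E1"))
  expect_error(assemble_kernel_set(pan2, recs_bad), "ghost")
})

test_that("kernel matrices round-trip through dense TSV", {
  pan <- make_test_panel(n = 6, p = 15, seed = 16)
  recs <- data.frame(individual_id = pan$individual_ids,
                     environment = rep(c("E1", "E2"), 3))
  kset <- assemble_kernel_set(pan, recs)
  tmp <- tempfile(fileext = ".tsv")
  write_kernel_tsv(kset, tmp)
  back <- read_kernel_tsv(tmp)
  expect_equal(unname(back), unname(kset$full), tolerance = 1e-12)
})
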