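test_that("genotype TSV round-trips, preserves missing calls, rejects bad input", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tm1\tm2", "a\t0\t1", "b\t2\tNA"), tmp)
  suppressMessages(panel <- read_genotypes(tmp))
  expect_equal(unname(panel$calls), matrix(c(0, 2, 1, NA), 2, 2))
  expect_equal(sum(is.na(panel$calls)), 1L)

  # empty file -> no records
  empty <- tempfile(fileext = ".tsv")
  writeLines("individual_id\tm1\tm2", empty)
  expect_error(suppressMessages(read_genotypes(empty)), "no records")

  # bad token named by row and column
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tm1", "a\t0", "b\t7"), bad)
  expect_error(suppressMessages(read_genotypes(bad)), "'7'.*row 2.*m1")

  # duplicate ids rejected
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tm1", "a\t0", "a\t1"), dup)
  expect_error(suppressMessages(read_genotypes(dup)), "duplicate")

  # write -> read identity on a simulated panel with missing calls
  sim <- make_test_panel(n = 15, p = 30, miss = 0.1, seed = 42)
  out <- tempfile(fileext = ".csv")
  write_genotypes(sim, out, dialect = "csv")
  suppressMessages(back <- read_genotypes(out, dialect = "csv"))
  expect_identical(back$calls, sim$calls)
  expect_identical(back$marker_ids, sim$marker_ids)
})

test_that("missing-rate filter uses a strict threshold and matches a recount oracle", {
  calls <- cbind(c(0, NA, NA, NA), c(1, 2, NA, NA), c(0, 1, 2, 0))
  panel <- genotype_panel(calls, marker_ids = c("a", "b", "c"))
  # 3/4 missing > 0.5 -> removed; exactly 2/4 = 0.5 -> retained
  kept <- filter_missing(panel, max_missing = 0.5)
  expect_identical(kept$marker_ids, c("b", "c"))

  all_bad <- genotype_panel(cbind(c(0, NA, NA), c(NA, 1, NA)))
  expect_error(filter_missing(all_bad, max_missing = 0.5), "all markers")

  pan <- make_test_panel(n = 20, p = 60, miss = 0.3, seed = 7)
  thr <- 0.25
  surv <- filter_missing(pan, thr)$marker_ids
  oracle <- character()
  for (l in seq_len(ncol(pan$calls))) {
    frac <- sum(is.na(pan$calls[, l])) / nrow(pan$calls)
    if (frac <= thr) oracle <- c(oracle, pan$marker_ids[l])
  }
  expect_identical(surv, oracle)
})

test_that("marker-mean imputation fills with per-column observed means only", {
  panel <- genotype_panel(cbind(c(0, 2, NA), c(2, 2, NA)))
  imp <- impute_marker_mean(panel)
  expect_equal(unname(imp$calls[3, ]), c(1, 2))

  pan <- make_test_panel(n = 25, p = 40, miss = 0.2, seed = 9)
  imp <- impute_marker_mean(pan)
  expect_false(anyNA(imp$calls))
  for (l in seq_len(ncol(pan$calls))) {
    obs <- !is.na(pan$calls[, l])
    # observed calls unchanged
    expect_identical(imp$calls[obs, l], pan$calls[obs, l])
    # imputed values equal the independent per-column mean
    if (any(!obs)) {
      expect_equal(unname(unique(imp$calls[!obs, l])),
                   mean(pan$calls[obs, l]))
    }
  }

  full_na <- genotype_panel(cbind(c(0, 1), c(NA, NA)),
                            marker_ids = c("ok", "gone"))
  expect_error(impute_marker_mean(full_na), "gone")
})

test_that("MAF computation is bounded, side-invariant and matches simulated truth", {
  panel <- genotype_panel(cbind(c(0, 0, 2), c(0, 0, 0)))
  expect_equal(unname(compute_maf(panel)), c(1 / 3, 0))

  pan <- impute_marker_mean(make_test_panel(20, 50, miss = 0.1, seed = 3))
  maf <- compute_maf(pan)
  expect_true(all(maf >= 0 & maf <= 0.5))
  flipped <- genotype_panel(2 - pan$calls)
  expect_equal(unname(compute_maf(flipped)), unname(maf))

  # empirical MAF close to generating allele frequency
  set.seed(11)
  n <- 400
  freq <- runif(30, 0.05, 0.5)
  calls <- sapply(freq, function(f) rbinom(n, 2, f))
  est <- compute_maf(genotype_panel(calls))
  tol <- 4 * sqrt(freq * (1 - freq) / (2 * n))
  expect_true(all(abs(est - freq) < pmax(tol, 0.05)))
})
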