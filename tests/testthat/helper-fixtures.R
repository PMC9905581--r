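# Small in-code fixtures shared across the suite.

# Random dosage panel with optional missingness.
make_test_panel <- function(n = 12, p = 20, miss = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (miss > 0) {
    idx <- sample(length(calls), round(miss * length(calls)))
    calls[idx] <- NA
  }
  genotype_panel(calls,
                 individual_ids = sprintf("i%02d", seq_len(n)),
                 marker_ids = sprintf("m%03d", seq_len(p)))
}

# Stacked multi-environment phenotype table over a shared-lines panel.
make_test_phenos <- function(panel, m = 2, seed = 1) {
  set.seed(seed)
  ids <- rep(panel$individual_ids, times = m)
  env <- rep(paste0("E", seq_len(m)), each = length(panel$individual_ids))
  phenotype_table(data.frame(
    individual_id = ids, environment = env, trait = "trait1",
    value = rnorm(length(ids)), stringsAsFactors = FALSE))
}

# Independent double-loop oracle for the (weighted) squared distance.
loop_sqdist <- function(a, b, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(a))
  d2 <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (k in seq_len(nrow(b))) {
      d2[i, k] <- sum(w * (a[i, ] - b[k, ])^2)
    }
  }
  d2
}

# Independent sort-and-cummin implementation of BH step-up adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Hand-built me_fit with constant parameter draws, for testing the
# conditional-prediction algebra in isolation from any sampler.
make_const_me_fit <- function(y, records, envs, mu, G_env, S_b, sigma2_e,
                              nd = 4) {
  m <- length(envs)
  structure(list(
    draws = list(
      mu = matrix(mu, nd, m, byrow = TRUE),
      sigma2_e = matrix(sigma2_e, nd, m, byrow = TRUE),
      G_env = matrix(as.vector(G_env), nd, m * m, byrow = TRUE),
      S_b = matrix(as.vector(S_b), nd, m * m, byrow = TRUE)),
    g = matrix(0, length(y), nd), b = matrix(0, length(y), nd),
    environments = envs, records = records, y = y,
    meta = list(regime = "general", iters = nd * 10, burnin = 0,
                thin = 10, m = m, n = length(y))),
    class = "me_fit")
}
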