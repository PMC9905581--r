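# Scaled-inverse-chi-square draw: df * scale / chisq(df)
rsinvchi2 <- function(df, scale) {
  (df * scale) / stats::rchisq(1L, df)
}

# Symmetric eigendecomposition with small-eigenvalue clamping; errors on
# clearly indefinite input.
eigen_psd <- function(M, label) {
  e <- eigen(M, symmetric = TRUE)
  tol <- -1e-6 * max(abs(e$values), 1)
  if (min(e$values) < tol) {
    stop(label, " is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  }
  e$values <- pmax(e$values, 1e-10 * max(e$values, 1))
  e
}

#' Fit the single-environment Bayesian kernel model
#'
#' Gibbs sampler for the model `y = 1 mu + g + b + e` with
#' `g ~ N(0, sigma2_g K)`, `b ~ N(0, sigma2_b B)` and
#' `e ~ N(0, sigma2_e I)`. The mean gets a flat prior; the three variances
#' get weakly informative scaled-inverse-chi-square priors (df 5, scale
#' half the phenotypic variance). Sampling uses the eigendecompositions of
#' `K` and `B`, so each sweep costs O(n^2).
#'
#' @param y numeric response vector for one environment.
#' @param K n x n positive semidefinite kernel matrix.
#' @param B optional n x n background relationship matrix (default
#'   identity).
#' @param iters,burnin total Gibbs iterations and burn-in (defaults
#'   12000 / 6000).
#' @param thin thinning interval for stored draws (default 10).
#' @param seed optional integer seed; equal seeds give identical chains.
#' @return Object of class `se_fit` with elements `draws` (data.frame of
#'   thinned draws of `mu`, `sigma2_g`, `sigma2_b`, `sigma2_e`), `g`, `b`
#'   (matrices of thinned latent draws, records x draws), `meta`.
#' @export
fit_se <- function(y, K, B = NULL, iters = 12000, burnin = 6000, thin = 10,
                   seed = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, iters > burnin, burnin >= 1)
  if (!is.null(seed)) set.seed(seed)
  eK <- eigen_psd(K, "kernel matrix")
  identity_B <- is.null(B)
  if (!identity_B) {
    stopifnot(nrow(B) == n, ncol(B) == n)
    eB <- eigen_psd(B, "background matrix")
  }
  vy <- stats::var(y)
  if (vy <= 0) stop("response has zero variance")
  df0 <- 5; S0 <- vy / 2

  mu <- mean(y)
  sig_g <- sig_b <- sig_e <- vy / 3
  gam <- numeric(n)                      # g in the K eigenbasis
  g <- numeric(n)
  b <- numeric(n)

  n_store <- floor((iters - burnin) / thin)
  dr <- matrix(NA_real_, n_store, 4,
               dimnames = list(NULL, c("mu", "sigma2_g", "sigma2_b",
                                       "sigma2_e")))
  g_dr <- matrix(NA_real_, n, n_store)
  b_dr <- matrix(NA_real_, n, n_store)
  s <- 0L

  for (it in seq_len(iters)) {
    # g | .
    r <- crossprod(eK$vectors, y - mu - b)[, 1L]
    v <- 1 / (1 / (sig_g * eK$values) + 1 / sig_e)
    gam <- v * r / sig_e + sqrt(v) * stats::rnorm(n)
    g <- as.vector(eK$vectors %*% gam)
    # b | .
    r2 <- y - mu - g
    if (identity_B) {
      v <- 1 / (1 / sig_b + 1 / sig_e)
      b <- v * r2 / sig_e + sqrt(v) * stats::rnorm(n)
      ss_b <- sum(b^2)
    } else {
      r2t <- crossprod(eB$vectors, r2)[, 1L]
      v <- 1 / (1 / (sig_b * eB$values) + 1 / sig_e)
      bt <- v * r2t / sig_e + sqrt(v) * stats::rnorm(n)
      b <- as.vector(eB$vectors %*% bt)
      ss_b <- sum(bt^2 / eB$values)
    }
    # mu | .
    r3 <- y - g - b
    mu <- stats::rnorm(1L, mean(r3), sqrt(sig_e / n))
    # variances | .
    sig_g <- (df0 * S0 + sum(gam^2 / eK$values)) /
      stats::rchisq(1L, df0 + n)
    sig_b <- (df0 * S0 + ss_b) / stats::rchisq(1L, df0 + n)
    sig_e <- (df0 * S0 + sum((y - mu - g - b)^2)) /
      stats::rchisq(1L, df0 + n)
    if (!is.finite(mu) || !is.finite(sig_g) || !is.finite(sig_b) ||
        !is.finite(sig_e)) {
      stop("divergent chain at iteration ", it)
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      s <- s + 1L
      dr[s, ] <- c(mu, sig_g, sig_b, sig_e)
      g_dr[, s] <- g
      b_dr[, s] <- b
    }
  }

  structure(
    list(draws = as.data.frame(dr), g = g_dr, b = b_dr,
         y = y, K = K, B = B,
         meta = list(iters = iters, burnin = burnin, thin = thin,
                     seed = seed, n = n)),
    class = "se_fit"
  )
}

#' @export
print.se_fit <- function(x, ...) {
  cat("Single-environment Bayesian kernel fit\n")
  cat(sprintf("  n = %d, iterations = %d (burn-in %d, thin %d), draws = %d\n",
              x$meta$n, x$meta$iters, x$meta$burnin, x$meta$thin,
              nrow(x$draws)))
  pm <- colMeans(x$draws)
  cat(sprintf("  posterior means: mu = %.3f, sigma2_g = %.3f, sigma2_b = %.3f, sigma2_e = %.3f\n",
              pm["mu"], pm["sigma2_g"], pm["sigma2_b"], pm["sigma2_e"]))
  cat(sprintf("  h2 (genomic) = %.3f\n", estimate_h2(x)))
  invisible(x)
}

#' @export
coef.se_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' @export
summary.se_fit <- function(object, ...) {
  qs <- t(apply(object$draws, 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(mean = colMeans(object$draws), qs, check.names = FALSE)
  out$ess <- chain_diagnostics(object$draws)
  out$rhat <- split_rhat(object$draws)
  out
}

#' @export
residuals.se_fit <- function(object, ...) {
  pm <- colMeans(object$draws)
  object$y - pm["mu"] - rowMeans(object$g) - rowMeans(object$b)
}

#' @export
plot.se_fit <- function(x, pars = colnames(x$draws), ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::plot(x$draws[[p]], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Predict held-out phenotypes from a single-environment fit
#'
#' Conditional-mean prediction under the fitted model: for each stored
#' posterior draw, `mu + C V^-1 (y_trn - mu)` where `V` is the training
#' covariance `sigma2_g K + sigma2_b B + sigma2_e I` and `C` the
#' genetic-plus-background cross-covariance between new and training
#' records; the draws are averaged.
#'
#' @param object an `se_fit`.
#' @param K_new_train kernel block between new and training records.
#' @param B_new_train optional background block (defaults to zero, the
#'   identity-mode convention for unseen records).
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.se_fit <- function(object, K_new_train, B_new_train = NULL, ...) {
  n <- object$meta$n
  y <- object$y
  preds <- matrix(0, nrow(K_new_train), nrow(object$draws))
  for (s in seq_len(nrow(object$draws))) {
    d <- object$draws[s, ]
    V <- d$sigma2_g * object$K + diag(d$sigma2_e, n)
    V <- V + if (is.null(object$B)) diag(d$sigma2_b, n) else d$sigma2_b * object$B
    C <- d$sigma2_g * K_new_train
    if (!is.null(B_new_train)) C <- C + d$sigma2_b * B_new_train
    preds[, s] <- d$mu + C %*% solve_chol_ridge(V, y - d$mu)
  }
  rowMeans(preds)
}

# Solve V x = r by Cholesky, retrying once with a 1e-8 ridge.
solve_chol_ridge <- function(V, r) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), nrow(V))),
                   error = function(e) stop("singular training covariance"))
  }
  backsolve(ch, forwardsolve(t(ch), r))
}

# Effective sample sizes of chain columns (coda if available, else a
# simple autocorrelation-based estimate).
chain_diagnostics <- function(draws) {
  if (requireNamespace("coda", quietly = TRUE)) {
    as.numeric(coda::effectiveSize(coda::mcmc(as.matrix(draws))))
  } else {
    vapply(as.data.frame(draws), function(v) {
      n <- length(v)
      ac <- stats::acf(v, plot = FALSE, lag.max = min(100, n - 1))$acf[-1]
      pos <- ac[ac > 0.05]
      n / (1 + 2 * sum(pos))
    }, numeric(1))
  }
}

# Split-chain convergence statistic (potential scale reduction computed by
# splitting each trace in half).
split_rhat <- function(draws) {
  vapply(as.data.frame(draws), function(v) {
    n2 <- floor(length(v) / 2)
    halves <- cbind(v[seq_len(n2)], v[seq_len(n2) + n2])
    W <- mean(apply(halves, 2L, stats::var))
    Bn <- n2 * stats::var(colMeans(halves))
    if (W <= 0) return(NA_real_)
    sqrt(((n2 - 1) / n2 * W + Bn / n2) / W)
  }, numeric(1))
}

#' Write thinned posterior draws as long-format TSV (draw, parameter, value)
#' @param fit an `se_fit` or `me_fit`.
#' @param path output path.
#' @export
write_draws_tsv <- function(fit, path) {
  flat <- if (inherits(fit, "se_fit")) {
    as.matrix(fit$draws)
  } else {
    m <- fit$meta$m
    out <- cbind(fit$draws$mu, fit$draws$sigma2_e, fit$draws$G_env,
                 fit$draws$S_b)
    colnames(out) <- c(paste0("mu_", fit$environments),
                       paste0("sigma2_e_", fit$environments),
                       paste0("G_env_", as.vector(outer(fit$environments,
                         fit$environments, paste, sep = "."))),
                       paste0("S_b_", as.vector(outer(fit$environments,
                         fit$environments, paste, sep = "."))))
    out
  }
  long <- data.frame(
    draw = rep(seq_len(nrow(flat)), times = ncol(flat)),
    parameter = rep(colnames(flat), each = nrow(flat)),
    value = as.vector(flat))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
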