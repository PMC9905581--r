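#' Fit the generalized multi-environment Bayesian kernel model
#'
#' Gibbs sampler for `y = mu + g + b + e` over the stacked records of all
#' environments, where the genetic effect has covariance built from an
#' environment-level genetic covariance matrix (variances `sigma2_g_j`,
#' covariances `sigma_g_jk`) expanded over the kernel blocks `K_jk`, the
#' background effect uses the background relationship blocks analogously,
#' and residuals are independent with per-environment variances.
#'
#' Two sampling regimes are available:
#' \describe{
#'   \item{`kronecker`}{for designs where the same individuals are
#'     phenotyped in every environment (e.g. doubled-haploid lines). The
#'     genetic covariance is then the Kronecker product of the environment
#'     covariance and one kernel, the environment covariance gets a
#'     conjugate inverse-Wishart update, and sampling runs in the kernel
#'     eigenbasis (fast). Defaults: 20000 iterations, 10000 burn-in.
#'     Background cross-environment covariances are fixed at zero in this
#'     regime.}
#'   \item{`general`}{for disjoint individuals per environment (e.g.
#'     half-sib families spanning sites). The environment genetic
#'     covariance is updated by Metropolis-within-Gibbs random walks on
#'     log-variances and Fisher-z correlations (proposal scale adapted to
#'     a 20-45\% acceptance rate during burn-in, then frozen); with a
#'     half-sib background the background covariance parameters are
#'     updated the same way. Defaults: 100000 iterations, 50000 burn-in.}
#' }
#'
#' Priors: flat on the means; scaled-inverse-chi-square (df 5, scale half
#' the per-environment phenotypic variance) on every scalar variance;
#' inverse-Wishart (df m + 2, scale diag of half phenotypic variances) on
#' the environment genetic covariance in the Kronecker regime; uniform(-1,
#' 1) on its correlations in the general regime.
#'
#' @param phenos a [phenotype_table()] (restricted to `trait` if it has
#'   several) whose records match `kernel_set$records`.
#' @param kernel_set a [assemble_kernel_set()] result covering the records.
#' @param background optional [build_background()] result over the same
#'   records; default identity.
#' @param regime `"auto"` (Kronecker when every environment has the same
#'   individual set), `"kronecker"` or `"general"`.
#' @param iters,burnin iterations and burn-in; regime-specific defaults.
#' @param thin thinning for stored draws (default 10).
#' @param seed optional integer seed; chains are reproducible given seed.
#' @param trait optional trait id when `phenos` has several traits.
#' @return Object of class `me_fit` with `draws` (list of matrices: `mu`,
#'   `sigma2_e` with one column per environment, `G_env` and `S_b` with
#'   `m^2` columns in row-major block order), `g`, `b` (records x draws),
#'   `environments`, `records`, `y`, `meta`.
#' @export
fit_me <- function(phenos, kernel_set, background = NULL,
                   regime = c("auto", "kronecker", "general"),
                   iters = NULL, burnin = NULL, thin = 10, seed = NULL,
                   trait = NULL) {
  regime <- match.arg(regime)
  stopifnot(inherits(kernel_set, "kernel_set"))
  ph <- as.data.frame(phenos)
  if (!is.null(trait)) ph <- ph[ph$trait == trait, , drop = FALSE]
  if ("trait" %in% colnames(ph) && length(unique(ph$trait)) > 1L) {
    stop("phenotype table has several traits; pass 'trait'")
  }
  recs <- kernel_set$records
  key_k <- paste(recs$individual_id, recs$environment, sep = "\r")
  key_p <- paste(ph$individual_id, ph$environment, sep = "\r")
  idx <- match(key_k, key_p)
  if (anyNA(idx)) stop("kernel records without phenotype record")
  y <- ph$value[idx]
  env_lab <- recs$environment
  envs <- kernel_set$environments
  m <- length(envs)
  env_i <- match(env_lab, envs)

  if (is.null(background)) background <- build_background(recs)
  stopifnot(inherits(background, "background_matrix"))
  if (nrow(background$full) != length(y)) {
    stop("background matrix does not cover the kernel records")
  }

  shared <- m > 1L && {
    sets <- split(recs$individual_id, env_lab)
    all(vapply(sets, function(s) setequal(s, sets[[1L]]) &&
                 !anyDuplicated(s), logical(1)))
  }
  if (regime == "auto") regime <- if (shared) "kronecker" else "general"
  if (regime == "kronecker" && !shared) {
    stop("kronecker regime requires identical individual sets in every environment")
  }
  if (is.null(iters)) iters <- if (regime == "kronecker") 20000L else 100000L
  if (is.null(burnin)) burnin <- iters %/% 2L
  stopifnot(iters > burnin)
  if (!is.null(seed)) set.seed(seed)

  fit <- if (regime == "kronecker") {
    fit_me_kronecker(y, env_i, recs, kernel_set, background, m,
                     iters, burnin, thin)
  } else {
    fit_me_general(y, env_i, recs, kernel_set, background, m,
                   iters, burnin, thin)
  }
  fit$environments <- envs
  fit$records <- recs
  fit$y <- y
  fit$kernel_set <- kernel_set
  fit$background <- background
  fit$meta <- c(fit$meta,
                list(regime = regime, iters = iters, burnin = burnin,
                     thin = thin, seed = seed, m = m, n = length(y)))
  class(fit) <- "me_fit"
  fit
}

# Kronecker-regime sampler: same lines in every environment, identity-mode
# cross-environment background. Runs in the eigenbasis of the line kernel.
fit_me_kronecker <- function(y, env_i, recs, kernel_set, background, m,
                             iters, burnin, thin) {
  lines1 <- recs$individual_id[env_i == 1L]
  n <- length(lines1)
  # response matrix lines x environments, and record index per cell
  rec_of <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    rows <- which(env_i == j)
    pos <- match(lines1, recs$individual_id[rows])
    rec_of[, j] <- rows[pos]
  }
  Y <- matrix(y[rec_of], n, m)
  K <- kernel_set$full[rec_of[, 1L], rec_of[, 1L]]
  B <- background$full[rec_of[, 1L], rec_of[, 1L]]
  if (background$mode == "half_sib") {
    # within-environment background blocks only; cross blocks fixed at zero
    eB <- eigen_psd(B, "background matrix")
    identity_B <- FALSE
  } else {
    identity_B <- TRUE
  }
  eK <- eigen_psd(K, "kernel matrix")
  dK <- eK$values
  UK <- eK$vectors

  vy <- apply(Y, 2L, stats::var)
  if (any(vy <= 0)) stop("zero phenotypic variance in an environment")
  df0 <- 5
  S0e <- S0b <- vy / 2
  nu0 <- m + 2
  S0G <- diag(vy / 2, m)

  mu <- colMeans(Y)
  sig_e <- sig_b <- vy / 3
  G_env <- diag(vy / 3, m)
  Gmat <- matrix(0, n, m)   # genetic effects, line x environment
  Bmat <- matrix(0, n, m)

  n_store <- (iters - burnin) %/% thin
  mu_dr <- se_dr <- matrix(NA_real_, n_store, m)
  Gv_dr <- Sb_dr <- matrix(NA_real_, n_store, m * m)
  g_dr <- b_dr <- matrix(NA_real_, n * m, n_store)
  s <- 0L

  for (it in seq_len(iters)) {
    # genetic effects in the kernel eigenbasis; rows independent given G_env
    R <- Y - rep(mu, each = n) - Bmat
    Rt <- crossprod(UK, R)
    A <- chol2inv(chol(G_env))
    cs <- sqrt(sig_e)
    M <- (A * rep(cs, each = m)) * rep(cs, times = m)  # C^-1/2 A C^-1/2
    eM <- eigen(M, symmetric = TRUE)
    lam <- pmax(eM$values, 0)
    Q <- eM$vectors
    Dmat <- dK / outer(dK, lam, "+")       # n x m : d_i / (lambda_k + d_i)
    Tm <- (Rt / rep(cs, each = n)) %*% Q   # R~ C^{1/2}... (C^{1/2}=1/sqrt(sige))
    Mean <- (Tm * Dmat) %*% t(Q) * rep(cs, each = n)
    # draw: cov P_i^-1 = C^-1/2 Q D_i Q' C^-1/2 with D_i = d_i/(lam+d_i)
    Z <- matrix(stats::rnorm(n * m), n, m)
    Gt <- Mean + ((Z * sqrt(Dmat)) %*% t(Q)) * rep(cs, each = n)
    Gmat <- UK %*% Gt
    # environment genetic covariance | Gt : inverse-Wishart
    Spost <- S0G + crossprod(Gt, Gt / dK)
    W <- stats::rWishart(1L, nu0 + n, chol2inv(chol(Spost)))[, , 1L]
    G_env <- chol2inv(chol(W))
    G_env <- (G_env + t(G_env)) / 2
    # background effects and variances (cross-environment covariance zero)
    R2 <- Y - rep(mu, each = n) - Gmat
    for (j in seq_len(m)) {
      if (identity_B) {
        v <- 1 / (1 / sig_b[j] + 1 / sig_e[j])
        Bmat[, j] <- v * R2[, j] / sig_e[j] + sqrt(v) * stats::rnorm(n)
        ss_b <- sum(Bmat[, j]^2)
      } else {
        r2t <- crossprod(eB$vectors, R2[, j])[, 1L]
        v <- 1 / (1 / (sig_b[j] * eB$values) + 1 / sig_e[j])
        bt <- v * r2t / sig_e[j] + sqrt(v) * stats::rnorm(n)
        Bmat[, j] <- as.vector(eB$vectors %*% bt)
        ss_b <- sum(bt^2 / eB$values)
      }
      sig_b[j] <- (df0 * S0b[j] + ss_b) / stats::rchisq(1L, df0 + n)
    }
    # means and residual variances
    R3 <- Y - Gmat - Bmat
    for (j in seq_len(m)) {
      mu[j] <- stats::rnorm(1L, mean(R3[, j]), sqrt(sig_e[j] / n))
      ss <- sum((R3[, j] - mu[j])^2)
      sig_e[j] <- (df0 * S0e[j] + ss) / stats::rchisq(1L, df0 + n)
    }
    if (!all(is.finite(mu)) || !all(is.finite(sig_e)) ||
        !all(is.finite(G_env))) {
      stop("divergent chain at iteration ", it)
    }
    if (it > burnin && (it - burnin) %% thin == 0L && s < n_store) {
      s <- s + 1L
      mu_dr[s, ] <- mu
      se_dr[s, ] <- sig_e
      Gv_dr[s, ] <- as.vector(G_env)
      Sb_dr[s, ] <- as.vector(diag(sig_b, m))
      grec <- numeric(n * m); brec <- numeric(n * m)
      grec[rec_of] <- Gmat
      brec[rec_of] <- Bmat
      g_dr[, s] <- grec
      b_dr[, s] <- brec
    }
  }
  list(draws = list(mu = mu_dr, sigma2_e = se_dr, G_env = Gv_dr,
                    S_b = Sb_dr),
       g = g_dr, b = b_dr, meta = list())
}

# General-regime driver around the compiled sampler.
fit_me_general <- function(y, env_i, recs, kernel_set, background, m,
                           iters, burnin, thin) {
  n <- length(y)
  vy <- tapply(y, env_i, stats::var)[as.character(seq_len(m))]
  if (any(!is.finite(vy) | vy <= 0)) {
    stop("zero phenotypic variance in an environment")
  }
  identity_B <- background$mode == "identity"
  fam <- if (identity_B) {
    integer(n)
  } else {
    as.integer(factor(background$family_of)) - 1L
  }
  res <- me_general_gibbs(
    y = y, env = as.integer(env_i) - 1L, m = m,
    K = kernel_set$full, B = background$full, fam = fam,
    background_identity = identity_B,
    iters = as.integer(iters), burnin = as.integer(burnin),
    thin = as.integer(thin),
    df0 = 5, S0g = vy / 2, S0b = vy / 2, S0e = vy / 2,
    step_g_init = 0.15, step_b_init = 0.3
  )
  if (isTRUE(res$dead_window)) {
    warning("an adaptation window had no accepted proposals; ",
            "inspect trace plots")
  }
  list(draws = list(mu = res$mu, sigma2_e = res$sigma2_e,
                    G_env = res$G_env, S_b = res$S_b),
       g = res$g, b = res$b,
       meta = list(accept_g = res$accept_g, accept_b = res$accept_b,
                   step_g = res$step_g, step_b = res$step_b))
}

#' @export
print.me_fit <- function(x, ...) {
  m <- x$meta$m
  cat("Multi-environment Bayesian kernel fit (", x$meta$regime,
      " regime)\n", sep = "")
  cat(sprintf("  n = %d records, %d environments; %d iterations (burn-in %d, thin %d)\n",
              x$meta$n, m, x$meta$iters, x$meta$burnin, x$meta$thin))
  G <- matrix(colMeans(x$draws$G_env), m, m,
              dimnames = list(x$environments, x$environments))
  cat("  posterior mean environment genetic covariance:\n")
  print(round(G, 4))
  cat("  posterior mean genetic correlations:\n")
  print(round(stats::cov2cor(G), 3))
  cat("  h2 per environment:",
      paste(sprintf("%s=%.3f", x$environments, estimate_h2(x)),
            collapse = ", "), "\n")
  if (!is.null(x$meta$accept_g) && is.finite(x$meta$accept_g)) {
    cat(sprintf("  MH acceptance (genetic covariance): %.2f\n",
                x$meta$accept_g))
  }
  invisible(x)
}

#' @export
coef.me_fit <- function(object, ...) {
  m <- object$meta$m
  list(mu = stats::setNames(colMeans(object$draws$mu), object$environments),
       G_env = matrix(colMeans(object$draws$G_env), m, m,
                      dimnames = list(object$environments,
                                      object$environments)),
       S_b = matrix(colMeans(object$draws$S_b), m, m,
                    dimnames = list(object$environments,
                                    object$environments)),
       sigma2_e = stats::setNames(colMeans(object$draws$sigma2_e),
                                  object$environments))
}

#' @export
summary.me_fit <- function(object, ...) {
  flat <- cbind(object$draws$mu, object$draws$sigma2_e,
                object$draws$G_env)
  colnames(flat) <- c(paste0("mu_", object$environments),
                      paste0("sigma2_e_", object$environments),
                      paste0("G_env_", as.vector(outer(
                        object$environments, object$environments, paste,
                        sep = "."))))
  qs <- t(apply(flat, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(mean = colMeans(flat), qs, ess = chain_diagnostics(flat),
             rhat = split_rhat(flat), check.names = FALSE)
}

#' @export
plot.me_fit <- function(x, ...) {
  m <- x$meta$m
  diag_ix <- (seq_len(m) - 1L) * m + seq_len(m)
  tr <- cbind(x$draws$G_env[, diag_ix, drop = FALSE], x$draws$sigma2_e)
  labs <- c(paste0("sigma2_g_", x$environments),
            paste0("sigma2_e_", x$environments))
  op <- graphics::par(mfrow = c(ncol(tr), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(ncol(tr))) {
    graphics::plot(tr[, i], type = "l", ylab = labs[i], xlab = "", ...)
  }
  invisible(x)
}

#' Conditional prediction of held-out records (CV2-style)
#'
#' For each stored posterior draw, computes the conditional mean of the
#' test records given the training phenotypes under the multivariate
#' normal implied by the fitted model with that draw's parameters, then
#' averages over draws:
#' `mu_TST + C V^-1 (y_TRN - mu_TRN)` with
#' `V = (Sigma_g + Sigma_b + Sigma_e)[TRN, TRN]` and
#' `C = (Sigma_g + Sigma_b)[TST, TRN]`.
#'
#' @param fit an `me_fit` trained on the `train_mask` records only.
#' @param kernel_set kernel set covering train and test records (one
#'   shared normalizer).
#' @param background background matrix over the same records.
#' @param train_mask,test_mask logical or integer masks over
#'   `kernel_set$records`.
#' @return Numeric vector of predictions for the test records (in
#'   `kernel_set$records[test_mask, ]` order).
#' @export
predict_cv2 <- function(fit, kernel_set, background, train_mask, test_mask) {
  stopifnot(inherits(fit, "me_fit"), inherits(kernel_set, "kernel_set"))
  recs <- kernel_set$records
  tr <- seq_len(nrow(recs))[train_mask]
  ts <- seq_len(nrow(recs))[test_mask]
  if (length(intersect(tr, ts))) stop("train and test masks overlap")
  # align the fit's training records with the kernel's training rows
  key_fit <- paste(fit$records$individual_id, fit$records$environment,
                   sep = "\r")
  key_tr <- paste(recs$individual_id[tr], recs$environment[tr], sep = "\r")
  ord <- match(key_tr, key_fit)
  if (anyNA(ord)) stop("training records of the kernel set do not match the fit")
  y_tr <- fit$y[ord]
  m <- fit$meta$m
  envs <- fit$environments
  env_all <- match(recs$environment, envs)
  if (anyNA(env_all)) stop("kernel set has environments unseen by the fit")
  K <- kernel_set$full
  B <- background$full
  env_tr <- env_all[tr]; env_ts <- env_all[ts]
  draws <- fit$draws
  nd <- nrow(draws$mu)
  Etr <- outer(env_tr, env_tr, function(a, b) (a - 1L) * m + b)
  Cts <- outer(env_ts, env_tr, function(a, b) (a - 1L) * m + b)
  preds <- matrix(0, length(ts), nd)
  for (s in seq_len(nd)) {
    Sg <- matrix(draws$G_env[s, ], m, m)
    Sb <- matrix(draws$S_b[s, ], m, m)
    sig_e <- draws$sigma2_e[s, ]
    Sg_flat <- as.vector(t(Sg)); Sb_flat <- as.vector(t(Sb))
    V <- Sg_flat[Etr] * K[tr, tr, drop = FALSE] +
      Sb_flat[Etr] * B[tr, tr, drop = FALSE]
    diag(V) <- diag(V) + sig_e[env_tr]
    C <- Sg_flat[Cts] * K[ts, tr, drop = FALSE] +
      Sb_flat[Cts] * B[ts, tr, drop = FALSE]
    mu <- draws$mu[s, ]
    preds[, s] <- mu[env_ts] + C %*% solve_chol_ridge(V, y_tr - mu[env_tr])
  }
  rowMeans(preds)
}

#' @export
predict.me_fit <- function(object, kernel_set = object$kernel_set,
                           background = object$background,
                           train_mask = NULL, test_mask = NULL, ...) {
  if (is.null(train_mask) || is.null(test_mask)) {
    stop("supply train_mask and test_mask (CV2-style conditional prediction)")
  }
  predict_cv2(object, kernel_set, background, train_mask, test_mask)
}

#' Write observed and predicted phenotypes as TSV
#' @param records data.frame with `individual_id`, `environment`.
#' @param observed,predicted numeric vectors aligned to `records`.
#' @param path output path.
#' @export
write_predictions_tsv <- function(records, observed, predicted, path) {
  df <- data.frame(individual_id = records$individual_id,
                   environment = records$environment,
                   observed = observed, predicted = predicted)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Narrow-sense heritability from a fitted model
#'
#' Posterior mean of `sigma2_g / (sigma2_g + sigma2_b + sigma2_e)` per
#' environment (the multi-environment version uses the per-environment
#' diagonal of the environment genetic covariance). For the GBLUP
#' convention fit the model with the additive linear kernel.
#'
#' @param fit an `se_fit` or `me_fit`.
#' @return Numeric vector of per-environment heritabilities in \[0, 1\].
#' @export
estimate_h2 <- function(fit) {
  if (inherits(fit, "se_fit")) {
    d <- fit$draws
    return(mean(d$sigma2_g / (d$sigma2_g + d$sigma2_b + d$sigma2_e)))
  }
  stopifnot(inherits(fit, "me_fit"))
  m <- fit$meta$m
  diag_ix <- (seq_len(m) - 1L) * m + seq_len(m)
  sg <- fit$draws$G_env[, diag_ix, drop = FALSE]
  sb <- fit$draws$S_b[, diag_ix, drop = FALSE]
  se <- fit$draws$sigma2_e
  stats::setNames(colMeans(sg / (sg + sb + se)), fit$environments)
}
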