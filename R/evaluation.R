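#' Random training/testing partitions for cross-environment validation
#'
#' Draws `n_reps` random 70/30 (by default) partitions of the records of
#' one trait. In `line` mode the sampling unit is the individual id and
#' the same held-out id set applies in every environment (the layout in
#' which n_70 x m records form the training set); in `cell` mode
#' (individual, environment) cells are sampled independently within each
#' environment.
#'
#' @param phenos a [phenotype_table()] restricted to one trait.
#' @param n_reps number of replicate partitions (default 50).
#' @param train_frac training fraction (default 0.7).
#' @param mode `"line"` or `"cell"`.
#' @param seed integer seed; partitions are reproducible given seed.
#' @return List of `cv_partition` objects, each with `train`, `test`
#'   (logical masks over the rows of `phenos`), `replicate`, `mode`,
#'   `seed`.
#' @export
make_partitions <- function(phenos, n_reps = 50, train_frac = 0.7,
                            mode = c("line", "cell"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(train_frac > 0, train_frac < 1)
  ph <- as.data.frame(phenos)
  if ("trait" %in% colnames(ph) && length(unique(ph$trait)) > 1L) {
    stop("restrict 'phenos' to one trait before partitioning")
  }
  n <- nrow(ph)
  envs <- unique(ph$environment)
  set.seed(seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    train <- logical(n)
    if (mode == "line") {
      ids <- unique(ph$individual_id)
      n_tr <- round(train_frac * length(ids))
      tr_ids <- sample(ids, n_tr)
      train <- ph$individual_id %in% tr_ids
    } else {
      for (e in envs) {
        rows <- which(ph$environment == e)
        n_tr <- round(train_frac * length(rows))
        train[sample(rows, n_tr)] <- TRUE
      }
    }
    test <- !train
    n_test_env <- tapply(test, ph$environment, sum)
    if (any(n_test_env < 5)) {
      stop("fewer than 5 test records in an environment; ",
           "reduce train_frac or use more data")
    }
    out[[r]] <- structure(
      list(train = train, test = test, replicate = r, mode = mode,
           seed = seed),
      class = "cv_partition"
    )
  }
  out
}

#' Pearson correlation between observed and predicted phenotypes
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\], or `NA` (flagged with a warning) if
#'   either vector has zero variance.
#' @export
pcor <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Mean squared error of predictions
#' @param observed,predicted numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  mean((observed - predicted)^2)
}

#' Choose the Beta shape on training data
#'
#' For each candidate `beta`, evaluates the weighted-kernel model on inner
#' 80/20 splits of the training records (5 repeats) and returns the value
#' with the highest mean inner-fold prediction correlation; ties break
#' toward the smaller `beta`. A grid of size 1 is returned without inner
#' evaluation.
#'
#' @param panel imputed [genotype_panel()].
#' @param phenos training-record [phenotype_table()] (one trait).
#' @param beta_grid candidate Beta shapes (default `c(12, 25, 50, 100,
#'   200)`).
#' @param scheme weight scheme (`"MAF_Pvalue"`, `"MAF"` or `"Pvalue"` --
#'   the latter ignores `beta`, the grid head is returned).
#' @param config a [run_config()] (controls sampler sizes for the inner
#'   fits).
#' @param seed integer seed for the inner splits.
#' @return List `(beta, inner)` where `inner` is the mean inner PCOR per
#'   grid value (`NULL` when no evaluation was needed).
#' @export
select_beta <- function(panel, phenos, beta_grid = c(12, 25, 50, 100, 200),
                        scheme = "MAF_Pvalue", config = run_config(),
                        seed = 1L) {
  stopifnot(length(beta_grid) >= 1)
  beta_grid <- sort(beta_grid)
  if (length(beta_grid) == 1L || scheme == "Pvalue") {
    return(list(beta = beta_grid[1L], inner = NULL))
  }
  ph <- as.data.frame(phenos)
  inner_seeds <- derive_seed(seed, seq_len(5L))
  score <- matrix(NA_real_, 5L, length(beta_grid))
  for (rep_i in seq_len(5L)) {
    part <- make_partitions(ph, n_reps = 1L, train_frac = 0.8,
                            mode = "line", seed = inner_seeds[rep_i])[[1L]]
    tr <- part$train
    for (bi in seq_along(beta_grid)) {
      res <- try(run_variant_once(panel, ph, tr, !tr, "ME_WK",
                                  scheme = scheme, beta = beta_grid[bi],
                                  config = config), silent = TRUE)
      if (!inherits(res, "try-error")) {
        score[rep_i, bi] <- mean(res$pcor, na.rm = TRUE)
      }
    }
  }
  avg <- colMeans(score, na.rm = TRUE)
  best <- which(avg >= max(avg, na.rm = TRUE) - 1e-12)[1L]  # ties -> smaller
  list(beta = beta_grid[best], inner = stats::setNames(avg, beta_grid))
}

# Fit one model variant on a train/test split and score it per environment.
# variant: "SE_GK" or "ME_*" with scheme NULL (GK) / weight scheme.
run_variant_once <- function(panel, ph, train, test, variant,
                             scheme = NULL, beta = 25, config = run_config()) {
  envs <- unique(ph$environment)
  train_ids <- unique(ph$individual_id[train])
  if (variant == "SE_GK") {
    pc <- ms <- stats::setNames(numeric(length(envs)), envs)
    for (e in envs) {
      rows_tr <- which(train & ph$environment == e)
      rows_ts <- which(test & ph$environment == e)
      ids_tr <- ph$individual_id[rows_tr]
      ids_ts <- ph$individual_id[rows_ts]
      X <- panel$calls[c(ids_tr, ids_ts), , drop = FALSE]
      kb <- gaussian_kernel(X, X, h = config$h)   # per-environment normalizer
      n_tr <- length(ids_tr)
      K_tr <- kb$K[seq_len(n_tr), seq_len(n_tr)]
      fit <- fit_se(ph$value[rows_tr], K_tr,
                    iters = config$se_iters, burnin = config$se_burnin,
                    thin = config$thin)
      pred <- predict(fit, kb$K[-seq_len(n_tr), seq_len(n_tr), drop = FALSE])
      pc[e] <- pcor(ph$value[rows_ts], pred)
      ms[e] <- mse(ph$value[rows_ts], pred)
    }
    return(list(pcor = pc, mse = ms))
  }
  # multi-environment variants: weights (if any) from training records only
  weights <- NULL
  if (!is.null(scheme)) {
    gw <- run_gwas(panel, ph, trait = ph$trait[1L], subset = train)
    maf <- compute_maf(subset_individuals(panel, train_ids))
    weights <- switch(scheme,
      MAF_Pvalue = weights_maf_pvalue(maf, gw$p_main_adj, gw$p_gxe_adj,
                                      alpha = config$alpha, beta = beta),
      MAF = weights_maf(maf, gw$p_main_adj, gw$p_gxe_adj,
                        alpha = config$alpha, beta = beta),
      Pvalue = weights_pvalue(gw$p_main_adj, gw$p_gxe_adj),
      stop("unknown weight scheme: ", scheme)
    )
  }
  kset <- assemble_kernel_set(panel, ph, weights = weights, h = config$h)
  bg <- if (config$background == "half_sib") {
    build_background(ph, families = panel$family_of, mode = "half_sib")
  } else {
    build_background(ph)
  }
  kset_tr <- subset_kernel_set(kset, train)
  bg_tr <- subset_background(bg, train)
  regime <- config$regime
  if (regime == "auto") {
    sets <- split(ph$individual_id[train], ph$environment[train])
    shared <- length(sets) > 1L &&
      all(vapply(sets, function(s) setequal(s, sets[[1L]]), logical(1)))
    regime <- if (shared) "kronecker" else "general"
  }
  it <- if (regime == "kronecker") config$me_iters else config$me_general_iters
  bu <- if (regime == "kronecker") config$me_burnin else config$me_general_burnin
  fit <- fit_me(ph[train, , drop = FALSE], kset_tr, bg_tr, regime = regime,
                iters = it, burnin = bu, thin = config$thin)
  pred <- predict_cv2(fit, kset, bg, train, test)
  obs <- ph$value[test]
  env_ts <- ph$environment[test]
  pc <- ms <- stats::setNames(rep(NA_real_, length(envs)), envs)
  for (e in envs) {
    sel <- env_ts == e
    if (sum(sel) >= 3) {
      pc[e] <- pcor(obs[sel], pred[sel])
      ms[e] <- mse(obs[sel], pred[sel])
    }
  }
  list(pcor = pc, mse = ms)
}

# Restrict a kernel_set / background to a record mask (keeps normalizer).
subset_kernel_set <- function(kset, mask) {
  ix <- seq_len(nrow(kset$records))[mask]
  recs <- kset$records[ix, , drop = FALSE]
  env <- recs$environment
  envs <- unique(env)
  blocks <- list()
  K <- kset$full[ix, ix, drop = FALSE]
  for (j in envs) for (k in envs) {
    blocks[[paste(j, k, sep = ".")]] <- K[env == j, env == k, drop = FALSE]
  }
  structure(list(full = K, blocks = blocks, environments = envs,
                 records = recs, h = kset$h, method = kset$method,
                 normalizer = kset$normalizer, weights = kset$weights),
            class = "kernel_set")
}

subset_background <- function(bg, mask) {
  ix <- seq_len(nrow(bg$records))[mask]
  structure(list(full = bg$full[ix, ix, drop = FALSE], mode = bg$mode,
                 records = bg$records[ix, , drop = FALSE],
                 family_of = bg$family_of[ix]),
            class = "background_matrix")
}

#' Run the cross-validation experiment comparing model variants
#'
#' For each random partition: recomputes allele frequencies and the
#' association scan on the training records only, rebuilds the kernels,
#' fits each requested model variant on the training records, predicts
#' the held-out records, and scores prediction correlation (PCOR) and
#' mean squared error (MSE) per environment. Results are aggregated over
#' replicates. A failed replicate is recorded and excluded with a
#' warning.
#'
#' @param panel imputed [genotype_panel()].
#' @param phenos a [phenotype_table()].
#' @param trait trait id.
#' @param variants subset of `c("SE_GK", "ME_GK", "ME_WK_MAF",
#'   "ME_WK_Pvalue", "ME_WK_MAF_Pvalue")`.
#' @param config a [run_config()].
#' @return Object of class `cv_report`: `results` (long data.frame:
#'   variant, environment, replicate, pcor, mse, beta), `summary`
#'   (aggregated means and standard errors), `failed` (replicate/variant
#'   pairs that errored).
#' @export
run_experiment <- function(panel, phenos, trait,
                           variants = c("SE_GK", "ME_GK",
                                        "ME_WK_MAF_Pvalue"),
                           config = run_config()) {
  all_variants <- c("SE_GK", "ME_GK", "ME_WK_MAF", "ME_WK_Pvalue",
                    "ME_WK_MAF_Pvalue")
  if (!all(variants %in% all_variants)) {
    stop("unknown variant(s): ",
         paste(setdiff(variants, all_variants), collapse = ", "))
  }
  ph <- as.data.frame(phenos)
  ph <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0L) stop("trait not found: ", trait)
  parts <- make_partitions(ph, n_reps = config$reps,
                           train_frac = config$train_frac,
                           mode = config$holdout,
                           seed = derive_seed(config$seed, 1L))
  rows <- list()
  failed <- list()
  for (r in seq_along(parts)) {
    part <- parts[[r]]
    for (v in variants) {
      scheme <- switch(v, SE_GK = NULL, ME_GK = NULL,
                       ME_WK_MAF = "MAF", ME_WK_Pvalue = "Pvalue",
                       ME_WK_MAF_Pvalue = "MAF_Pvalue")
      beta_sel <- NA_real_
      res <- tryCatch({
        set.seed(derive_seed(config$seed, 1000L + r))
        if (!is.null(scheme) && scheme != "Pvalue" &&
            length(config$beta_grid) > 1L) {
          sel <- select_beta(panel, ph[part$train, , drop = FALSE],
                             beta_grid = config$beta_grid, scheme = scheme,
                             config = config,
                             seed = derive_seed(config$seed, 2000L + r))
          beta_sel <- sel$beta
        } else {
          beta_sel <- config$beta_grid[1L]
        }
        run_variant_once(panel, ph, part$train, part$test, v,
                         scheme = scheme, beta = beta_sel, config = config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("replicate ", r, " variant ", v, " failed: ",
                conditionMessage(res), " (excluded)")
        failed[[length(failed) + 1L]] <- list(replicate = r, variant = v,
                                              message = conditionMessage(res))
        next
      }
      for (e in names(res$pcor)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, environment = e, replicate = r,
          pcor = res$pcor[[e]], mse = res$mse[[e]], beta = beta_sel,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(pcor, mse) ~ variant + environment,
                          data = results, FUN = mean, na.rm = TRUE)
  sem <- stats::aggregate(cbind(pcor, mse) ~ variant + environment,
                          data = results,
                          FUN = function(x) stats::sd(x, na.rm = TRUE) /
                            sqrt(sum(is.finite(x))))
  colnames(sem)[3:4] <- c("pcor_se", "mse_se")
  structure(
    list(results = results, summary = merge(agg, sem), failed = failed,
         trait = trait, config = config),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report, trait", x$trait, "\n")
  cat(sprintf("  %d replicate(s), %s holdout, train fraction %.2f\n",
              x$config$reps, x$config$holdout, x$config$train_frac))
  if (length(x$failed)) cat("  failed replicates:", length(x$failed), "\n")
  s <- x$summary
  s$pcor <- round(s$pcor, 3); s$mse <- round(s$mse, 3)
  s$pcor_se <- round(s$pcor_se, 3); s$mse_se <- round(s$mse_se, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) object$summary

#' Write a cv_report as tidy TSVs
#' @param report a `cv_report`.
#' @param dir output directory (created if needed).
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$results, file.path(dir, "cv_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "cv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
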