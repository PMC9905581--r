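#' Beta density used for rare-variant up-weighting
#'
#' Evaluates the Beta(alpha, beta) density at `x`. With `alpha = 1` (the
#' default used throughout) this is `beta * (1 - x)^(beta - 1)`, a density
#' that decreases in `x`, so markers with small minor allele frequency
#' receive large values.
#'
#' @param x value(s) in \[0, 1\] (typically a MAF).
#' @param alpha,beta positive shape parameters.
#' @return Nonnegative density value(s).
#' @export
beta_density <- function(x, alpha = 1, beta = 25) {
  stopifnot(alpha > 0, beta > 0)
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  stats::dbeta(x, shape1 = alpha, shape2 = beta)
}

#' Scaling constant of the MAF weight component
#'
#' The constant balances the Beta-density (frequency) component of the
#' marker weight against the association (p-value) components: it is the
#' global maximum of `1/(0.1 + p)` over both adjusted p-value vectors,
#' divided by the Beta density at the smallest MAF. With `alpha = 1`, when
#' both the smallest adjusted p-value and the smallest MAF approach 0, the
#' constant approaches `10 / beta`.
#'
#' @param pvalue1,pvalue2 FDR-adjusted p-value vectors (main genotypic
#'   effect and G x E interaction) of common length p.
#' @param maf per-marker minor allele frequencies in \[0, 0.5\].
#' @param alpha,beta Beta density shapes.
#' @return Positive scalar.
#' @export
compute_c1 <- function(pvalue1, pvalue2, maf, alpha = 1, beta = 25) {
  stopifnot(length(pvalue1) == length(pvalue2),
            length(maf) == length(pvalue1))
  if (any(pvalue1 < 0 | pvalue1 > 1) || any(pvalue2 < 0 | pvalue2 > 1)) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  num <- max(1 / (0.1 + pvalue1), 1 / (0.1 + pvalue2))
  den <- beta_density(min(maf), alpha, beta)
  if (den == 0) {
    stop("Beta density is zero at the minimum MAF; cannot form the scaling constant")
  }
  num / den
}

new_marker_weights <- function(w, scheme, alpha = NA_real_, beta = NA_real_,
                               c1 = NA_real_, pvalue1 = NULL, pvalue2 = NULL,
                               maf = NULL) {
  if (any(w < 0)) stop("marker weights must be nonnegative")
  structure(
    list(w = as.numeric(w), scheme = scheme, alpha = alpha, beta = beta,
         c1 = c1, pvalue1 = pvalue1, pvalue2 = pvalue2, maf = maf),
    class = "marker_weights"
  )
}

#' @export
print.marker_weights <- function(x, ...) {
  cat("Marker weights (", x$scheme, "), p = ", length(x$w), "\n", sep = "")
  if (!is.na(x$c1)) {
    cat(sprintf("  alpha = %g, beta = %g, c1 = %.4g\n", x$alpha, x$beta, x$c1))
  }
  cat(sprintf("  weight range [%.4g, %.4g]\n", min(x$w), max(x$w)))
  invisible(x)
}

#' Combined MAF + p-value marker weights
#'
#' Weight of marker l:
#' `w_l = (c1 * Beta(MAF_l; alpha, beta) + 1/(0.1 + p1_l) + 1/(0.1 + p2_l))^2`
#' with `c1` from [compute_c1()] on the same inputs. Both p-value vectors
#' must already be FDR-adjusted.
#'
#' @inheritParams compute_c1
#' @return A `marker_weights` object (scheme `"MAF_Pvalue"`).
#' @export
weights_maf_pvalue <- function(maf, pvalue1, pvalue2, alpha = 1, beta = 25) {
  c1 <- compute_c1(pvalue1, pvalue2, maf, alpha, beta)
  w <- (c1 * beta_density(maf, alpha, beta) +
          1 / (0.1 + pvalue1) + 1 / (0.1 + pvalue2))^2
  new_marker_weights(w, "MAF_Pvalue", alpha, beta, c1, pvalue1, pvalue2, maf)
}

#' MAF-only marker weights
#'
#' `w_l = (c1 * Beta(MAF_l; alpha, beta))^2`. The p-value vectors are used
#' only to form the scaling constant `c1`.
#'
#' @inheritParams compute_c1
#' @return A `marker_weights` object (scheme `"MAF"`).
#' @export
weights_maf <- function(maf, pvalue1, pvalue2, alpha = 1, beta = 25) {
  c1 <- compute_c1(pvalue1, pvalue2, maf, alpha, beta)
  w <- (c1 * beta_density(maf, alpha, beta))^2
  new_marker_weights(w, "MAF", alpha, beta, c1, maf = maf)
}

#' P-value-only marker weights
#'
#' `w_l = (1/(0.1 + p1_l) + 1/(0.1 + p2_l))^2`; no MAF dependence.
#'
#' @inheritParams compute_c1
#' @return A `marker_weights` object (scheme `"Pvalue"`).
#' @export
weights_pvalue <- function(pvalue1, pvalue2) {
  stopifnot(length(pvalue1) == length(pvalue2))
  if (any(pvalue1 < 0 | pvalue1 > 1) || any(pvalue2 < 0 | pvalue2 > 1)) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  w <- (1 / (0.1 + pvalue1) + 1 / (0.1 + pvalue2))^2
  new_marker_weights(w, "Pvalue", pvalue1 = pvalue1, pvalue2 = pvalue2)
}

#' Write per-marker weights as TSV
#' @param weights a `marker_weights` object.
#' @param marker_ids character vector of marker ids.
#' @param path output path.
#' @export
write_weights_tsv <- function(weights, marker_ids, path) {
  df <- data.frame(
    marker_id = marker_ids,
    maf = if (is.null(weights$maf)) NA_real_ else weights$maf,
    pvalue1_adj = if (is.null(weights$pvalue1)) NA_real_ else weights$pvalue1,
    pvalue2_adj = if (is.null(weights$pvalue2)) NA_real_ else weights$pvalue2,
    weight = weights$w
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Weighted squared-Euclidean cross-distance matrix; w = NULL means uniform.
weighted_sqdist <- function(a, b, w = NULL) {
  if (is.null(w)) {
    aa <- rowSums(a * a)
    bb <- rowSums(b * b)
    d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  } else {
    aw <- a * rep(w, each = nrow(a))
    aa <- rowSums(aw * a)
    bb <- rowSums((b * rep(w, each = nrow(b))) * b)
    d2 <- outer(aa, bb, "+") - 2 * tcrossprod(aw, b)
  }
  pmax(d2, 0)
}

#' Gaussian kernel block
#'
#' `K(x_i, x_k) = exp(-h * d2_ik / s)` where `d2_ik` is the squared
#' Euclidean distance between the marker-genotype vectors and `s` is the
#' largest `d2_ik`. When `normalizer` is supplied it is used as `s`
#' (the multi-environment assembler passes the maximum over all record
#' pairs so that every block shares one scale); otherwise `s` is the
#' maximum over the pairs of `rows_a` x `rows_b`.
#'
#' @param rows_a,rows_b numeric genotype matrices over the same marker set.
#' @param h positive bandwidth (default 1).
#' @param normalizer optional positive scalar `s`.
#' @return List with `K` (kernel block) and `normalizer` (the `s` used).
#' @export
gaussian_kernel <- function(rows_a, rows_b = rows_a, h = 1, normalizer = NULL) {
  stopifnot(h > 0, ncol(rows_a) == ncol(rows_b))
  d2 <- weighted_sqdist(as.matrix(rows_a), as.matrix(rows_b))
  s <- if (is.null(normalizer)) max(d2) else normalizer
  if (s <= 0) stop("degenerate input: all genotypes identical (max distance is 0)")
  list(K = exp(-h * d2 / s), normalizer = s)
}

#' Weighted kernel block
#'
#' As [gaussian_kernel()] but with the weighted squared distance
#' `d*2_ik = sum_l w_l (x_il - x_kl)^2`. With all weights equal to any
#' positive constant the result equals the Gaussian kernel (the constant
#' cancels in `d*2 / s*`).
#'
#' @inheritParams gaussian_kernel
#' @param weights a `marker_weights` object or nonnegative numeric vector.
#' @return List with `K` and `normalizer` (`s*`).
#' @export
weighted_kernel <- function(rows_a, rows_b = rows_a, weights, h = 1,
                            normalizer = NULL) {
  w <- if (inherits(weights, "marker_weights")) weights$w else as.numeric(weights)
  stopifnot(h > 0, ncol(rows_a) == ncol(rows_b))
  if (length(w) != ncol(rows_a)) stop("weight length must match marker count")
  if (any(w < 0)) stop("negative marker weight")
  d2 <- weighted_sqdist(as.matrix(rows_a), as.matrix(rows_b), w)
  s <- if (is.null(normalizer)) max(d2) else normalizer
  if (s <= 0) stop("degenerate input: weighted distances are all 0")
  list(K = exp(-h * d2 / s), normalizer = s)
}

#' Additive (linear) genomic relationship kernel
#'
#' VanRaden-style GBLUP kernel `ZZ' / c` with `Z` the column-centered dosage
#' matrix and `c = 2 * sum(f_l (1 - f_l))` over observed allele frequencies.
#' Used for heritability estimation under the GBLUP convention.
#'
#' @param rows_a,rows_b genotype matrices over the same markers.
#' @param freq optional allele frequencies used for centering/scaling;
#'   defaults to frequencies computed from `rows_a`.
#' @return List with `K` and `normalizer` (the scaling `c`).
#' @export
linear_kernel <- function(rows_a, rows_b = rows_a, freq = NULL) {
  a <- as.matrix(rows_a); b <- as.matrix(rows_b)
  stopifnot(ncol(a) == ncol(b))
  if (is.null(freq)) freq <- colMeans(a) / 2
  ctr <- 2 * freq
  c0 <- 2 * sum(freq * (1 - freq))
  if (c0 <= 0) stop("degenerate input: all markers monomorphic")
  Za <- sweep(a, 2L, ctr)
  Zb <- sweep(b, 2L, ctr)
  list(K = tcrossprod(Za, Zb) / c0, normalizer = c0)
}

#' Assemble within- and cross-environment kernel blocks over records
#'
#' Given the phenotyped records of a multi-environment trial, builds the
#' full kernel matrix over all records and exposes the per-environment-pair
#' blocks `K_jk`. A single shared normalizer (the maximum squared distance
#' over *all* record pairs) is used for every block so the assembled matrix
#' is a valid positive semidefinite kernel; within-environment diagonals
#' are exactly 1.
#'
#' @param panel an imputed [genotype_panel()].
#' @param records data.frame with columns `individual_id` and `environment`
#'   (one row per phenotyped record, e.g. a [phenotype_table()] restricted
#'   to one trait).
#' @param weights optional `marker_weights`; `NULL` gives the Gaussian
#'   kernel.
#' @param h bandwidth, default 1.
#' @param method `"gaussian"`/`"weighted"` (chosen automatically from
#'   `weights`) or `"linear"` for the additive GBLUP kernel.
#' @return An object of class `kernel_set`: `full` (n x n kernel over
#'   records), `blocks` (list indexed `"j.k"`), `environments`, `records`,
#'   `h`, `normalizer`.
#' @export
assemble_kernel_set <- function(panel, records, weights = NULL, h = 1,
                                method = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  records <- as.data.frame(records)
  if (!all(c("individual_id", "environment") %in% colnames(records))) {
    stop("'records' needs columns individual_id and environment")
  }
  ids <- as.character(records$individual_id)
  unknown <- setdiff(ids, panel$individual_ids)
  if (length(unknown)) {
    stop("record without genotype for individual(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (anyNA(panel$calls)) stop("panel has missing calls; impute first")
  if (is.null(method)) {
    method <- if (is.null(weights)) "gaussian" else "weighted"
  }
  method <- match.arg(method, c("gaussian", "weighted", "linear"))
  X <- panel$calls[ids, , drop = FALSE]
  kb <- switch(method,
    gaussian = gaussian_kernel(X, X, h = h),
    weighted = weighted_kernel(X, X, weights = weights, h = h),
    linear = linear_kernel(X, X)
  )
  env <- as.character(records$environment)
  envs <- unique(env)
  blocks <- list()
  for (j in envs) {
    for (k in envs) {
      blocks[[paste(j, k, sep = ".")]] <-
        kb$K[env == j, env == k, drop = FALSE]
    }
  }
  structure(
    list(full = kb$K, blocks = blocks, environments = envs,
         records = data.frame(individual_id = ids, environment = env,
                              stringsAsFactors = FALSE),
         h = h, method = method, normalizer = kb$normalizer,
         weights = weights),
    class = "kernel_set"
  )
}

#' @export
print.kernel_set <- function(x, ...) {
  n <- nrow(x$full)
  cat("Kernel set (", x$method, "): ", n, " records, ",
      length(x$environments), " environment(s)\n", sep = "")
  tab <- table(x$records$environment)
  cat("  records/environment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  h = %g, normalizer = %.4g\n", x$h, x$normalizer))
  invisible(x)
}

#' Extract one kernel block
#' @param kset a `kernel_set`.
#' @param j,k environment labels.
#' @return Matrix `K_jk`.
#' @export
kernel_block <- function(kset, j, k = j) {
  kset$blocks[[paste(j, k, sep = ".")]]
}

#' Write a kernel matrix as dense TSV with row/column ids
#' @param K matrix with dimnames, or a `kernel_set` (writes `full`).
#' @param path output path.
#' @export
write_kernel_tsv <- function(K, path) {
  if (inherits(K, "kernel_set")) {
    ids <- paste(K$records$individual_id, K$records$environment, sep = "@")
    K <- K$full
    dimnames(K) <- list(ids, ids)
  }
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense kernel TSV written by [write_kernel_tsv()]
#' @param path file path.
#' @return Numeric matrix with row/column ids as dimnames.
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  K <- as.matrix(df[, -1L, drop = FALSE])
  rownames(K) <- df[[1L]]
  K
}
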