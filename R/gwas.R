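#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone in the ordering of
#' the raw p-values. Thin wrapper over [stats::p.adjust()] so the weight
#' formulas always consume adjusted values.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-marker scan with genotype main effect and G x E interaction
#'
#' Fits, by least squares on the stacked (individual, environment) records,
#' the fixed-effects model
#' `value = intercept + environment + marker + marker:environment + error`
#' and returns the p-value of the marker main effect (t test, 1 df), the
#' joint F test of the `m - 1` interaction terms against the nested model
#' without them, and the marker main-effect estimate.
#'
#' A marker that is constant across the records gets both p-values set to 1
#' (flagged), keeping the weight vector aligned with the kernel's marker
#' set. Aliased interaction columns (e.g. a marker segregating in only one
#' environment) are dropped with a warning recorded in the result.
#'
#' @param y numeric response vector over stacked records.
#' @param env factor (or coercible) of environment labels per record.
#' @param x marker dosages aligned to the records.
#' @return List `(pvalue1, pvalue2, effect, flag)`.
#' @export
scan_marker <- function(y, env, x) {
  env <- factor(env)
  if (nlevels(env) < 2L) stop("at least 2 environments required")
  X0 <- stats::model.matrix(~env)
  Es <- env_sum_contrasts(env)
  scan_marker_fast(y, X0, Es, x)
}

# Sum-to-zero environment contrast columns (m - 1 of them), so that the
# marker main-effect coefficient estimates the slope averaged over
# environments -- invariant to environment relabeling, and zero for a
# pure crossover interaction.
env_sum_contrasts <- function(env) {
  lv <- sort(levels(env))
  C <- stats::contr.sum(length(lv))
  rownames(C) <- lv
  C[as.character(env), , drop = FALSE]
}

# Internal: X0 = model.matrix(~ env) and Es = sum-contrast columns,
# precomputed once per scan.
scan_marker_fast <- function(y, X0, Es, x) {
  n <- length(y)
  if (stats::var(x) == 0) {
    return(list(pvalue1 = 1, pvalue2 = 1, effect = 0, flag = "constant"))
  }
  Xr <- cbind(X0, x)                     # reduced: env + marker
  Xf <- cbind(Xr, Es * x)                # full: + marker:env
  qf <- qr(Xf)
  flag <- NA_character_
  if (qf$rank < ncol(Xf)) {
    keep <- qf$pivot[seq_len(qf$rank)]
    # never drop the marker main-effect column (index ncol(Xr))
    if (!(ncol(Xr) %in% keep)) {
      return(list(pvalue1 = 1, pvalue2 = 1, effect = 0, flag = "aliased_main"))
    }
    Xf <- Xf[, sort(keep), drop = FALSE]
    qf <- qr(Xf)
    flag <- "aliased_interaction_dropped"
  }
  cf <- qr.coef(qf, y)
  res_f <- y - qr.fitted(qf, y)
  rss_f <- sum(res_f^2)
  df_f <- n - qf$rank
  xcol <- match("x", colnames(Xf))
  if (is.na(xcol)) xcol <- ncol(X0) + 1L
  # t test of the marker main effect in the full model
  R <- qr.R(qf)
  Rinv <- backsolve(R, diag(ncol(Xf)))
  xtx_inv_diag <- rowSums(Rinv * Rinv)[order(qf$pivot[seq_len(qf$rank)])]
  sigma2 <- rss_f / df_f
  se <- sqrt(sigma2 * xtx_inv_diag[xcol])
  eff <- cf[xcol]
  p1 <- if (se > 0 && df_f > 0) {
    2 * stats::pt(abs(eff / se), df_f, lower.tail = FALSE)
  } else 1
  # joint F test of the interaction columns
  qr_r <- qr(Xr)
  rss_r <- sum((y - qr.fitted(qr_r, y))^2)
  df_int <- qf$rank - qr_r$rank
  p2 <- if (df_int > 0 && df_f > 0 && rss_f > 0) {
    Fstat <- ((rss_r - rss_f) / df_int) / (rss_f / df_f)
    stats::pf(Fstat, df_int, df_f, lower.tail = FALSE)
  } else 1
  list(pvalue1 = unname(p1), pvalue2 = unname(p2), effect = unname(eff),
       flag = flag)
}

#' Genome-wide G x E association scan
#'
#' Applies [scan_marker()] to every marker of the panel for one trait, then
#' FDR-adjusts the two raw p-value vectors separately. During
#' cross-validation pass `subset` so the scan sees training records only.
#'
#' @param panel an imputed [genotype_panel()].
#' @param phenos a [phenotype_table()].
#' @param trait trait id to scan.
#' @param subset optional logical/integer mask over the trait's records.
#' @return Data.frame of class `gwas_scan`: `marker_id`, `beta_hat`,
#'   `p_main_raw`, `p_gxe_raw`, `p_main_adj`, `p_gxe_adj`, `flag`.
#' @export
run_gwas <- function(panel, phenos, trait, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ph <- phenos[phenos$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0L) stop("trait not found: ", trait)
  if (!is.null(subset)) ph <- ph[subset, , drop = FALSE]
  ids <- as.character(ph$individual_id)
  unknown <- setdiff(ids, panel$individual_ids)
  if (length(unknown)) {
    stop("phenotyped individual(s) without genotype: ",
         paste(unique(unknown), collapse = ", "))
  }
  y <- ph$value
  env <- factor(ph$environment)
  if (nlevels(env) < 2L) stop("at least 2 environments required for the G x E scan")
  X <- panel$calls[ids, , drop = FALSE]
  X0 <- stats::model.matrix(~env)
  Es <- env_sum_contrasts(env)
  p <- ncol(X)
  p1 <- p2 <- eff <- numeric(p)
  flag <- character(p)
  for (l in seq_len(p)) {
    r <- scan_marker_fast(y, X0, Es, X[, l])
    p1[l] <- r$pvalue1; p2[l] <- r$pvalue2; eff[l] <- r$effect
    flag[l] <- if (is.na(r$flag)) "" else r$flag
  }
  out <- data.frame(
    marker_id = panel$marker_ids,
    beta_hat = eff,
    p_main_raw = p1, p_gxe_raw = p2,
    p_main_adj = fdr_adjust(p1), p_gxe_adj = fdr_adjust(p2),
    flag = flag, stringsAsFactors = FALSE
  )
  attr(out, "trait") <- trait
  attr(out, "fdr_level") <- 0.05
  class(out) <- c("gwas_scan", class(out))
  out
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("G x E association scan:", nrow(x), "markers, trait",
      attr(x, "trait"), "\n")
  cat("  markers with adjusted main-effect p < 0.05:",
      sum(x$p_main_adj < 0.05), "\n")
  cat("  markers with adjusted interaction p < 0.05:",
      sum(x$p_gxe_adj < 0.05), "\n")
  invisible(x)
}

#' Write a scan result as TSV
#' @param scan a `gwas_scan`.
#' @param path output path.
#' @export
write_gwas_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
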