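#' Construct a genotype panel
#'
#' A genotype panel holds a matrix of allelic dosages (individuals in rows,
#' biallelic markers in columns) coded 0, 1, 2 for AA, Aa and aa, with
#' optional per-individual environment and family labels. Missing calls are
#' `NA` until imputed; marker-mean imputation produces fractional dosages in
#' \[0, 2\], which are kept as-is because the Euclidean kernel distances
#' downstream accept them.
#'
#' @param calls numeric matrix, individuals x markers; entries in \[0, 2\] or
#'   `NA`. Dimnames, if present, are used as ids unless overridden.
#' @param individual_ids,marker_ids character vectors of unique ids.
#' @param env_of optional named character vector mapping individual id to
#'   environment label (disjoint-individual designs). Absent for designs in
#'   which the same lines are phenotyped in every environment.
#' @param family_of optional named character vector mapping individual id to
#'   family label (half-sib designs).
#' @return An object of class `genotype_panel` with elements `calls`,
#'   `individual_ids`, `marker_ids`, `env_of`, `family_of`.
#' @export
genotype_panel <- function(calls, individual_ids = rownames(calls),
                           marker_ids = colnames(calls),
                           env_of = NULL, family_of = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind_", seq_len(nrow(calls)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- paste0("mk_", seq_len(ncol(calls)))
  }
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != nrow(calls)) {
    stop("length of 'individual_ids' does not match nrow(calls)")
  }
  if (length(marker_ids) != ncol(calls)) {
    stop("length of 'marker_ids' does not match ncol(calls)")
  }
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  rng <- range(calls, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  dimnames(calls) <- list(individual_ids, marker_ids)
  if (!is.null(env_of)) {
    env_of <- env_of[individual_ids]
    if (anyNA(env_of)) stop("'env_of' must cover every individual")
  }
  if (!is.null(family_of)) {
    family_of <- family_of[individual_ids]
    if (anyNA(family_of)) stop("'family_of' must cover every individual")
  }
  structure(
    list(calls = calls, individual_ids = individual_ids,
         marker_ids = marker_ids, env_of = env_of, family_of = family_of),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat("Genotype panel:", length(x$individual_ids), "individuals x",
      length(x$marker_ids), "markers\n")
  cat("  missing calls:", n_miss,
      sprintf("(%.2f%%)", 100 * n_miss / length(x$calls)), "\n")
  if (!is.null(x$env_of)) {
    cat("  environments:", paste(unique(x$env_of), collapse = ", "), "\n")
  }
  if (!is.null(x$family_of)) {
    cat("  families:", length(unique(x$family_of)), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Subset the individuals of a genotype panel
#'
#' Returns a row-subset view of the panel. Used by the cross-validation
#' harness so allele frequencies and association scans can be recomputed
#' cheaply on the training individuals of each partition.
#'
#' @param panel a [genotype_panel()].
#' @param ids character vector of individual ids (or logical/integer index).
#' @return A `genotype_panel` restricted to `ids`; marker set unchanged.
#' @export
subset_individuals <- function(panel, ids) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(ids)) {
    missing_ids <- setdiff(ids, panel$individual_ids)
    if (length(missing_ids)) {
      stop("unknown individual ids: ", paste(missing_ids, collapse = ", "))
    }
  }
  calls <- panel$calls[ids, , drop = FALSE]
  genotype_panel(calls,
                 individual_ids = rownames(calls),
                 marker_ids = panel$marker_ids,
                 env_of = panel$env_of, family_of = panel$family_of)
}

#' Read a genotype matrix from TSV/CSV
#'
#' Expected layout: header row with marker ids, first column with individual
#' ids, remaining cells 0/1/2 or NA/empty for missing.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A [genotype_panel()] with missing entries preserved.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) stop("no records in ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  mk <- colnames(df)[-1L]
  if (anyDuplicated(mk)) stop("duplicate marker ids in ", path)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  ok <- is.na(raw) | raw %in% c("0", "1", "2")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-{0,1,2,NA} genotype token '%s' at row %d (%s), column %d (%s)",
                 raw[bad[1L], bad[2L]], bad[1L], ids[bad[1L]], bad[2L],
                 mk[bad[2L]]))
  }
  calls <- matrix(as.numeric(raw), nrow = nrow(raw),
                  dimnames = list(ids, mk))
  message(sprintf("read %d individuals x %d markers from %s",
                  nrow(calls), ncol(calls), path))
  genotype_panel(calls, individual_ids = ids, marker_ids = mk)
}

#' Write a genotype panel to TSV/CSV
#'
#' Inverse of [read_genotypes()]; lossless for observed calls when dosages
#' are integers (fractional imputed dosages are written with full precision
#' but `read_genotypes()` only accepts 0/1/2/NA, so write before imputing).
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_genotypes <- function(panel, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(panel, "genotype_panel"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(individual_id = panel$individual_ids,
                   panel$calls, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a multi-environment phenotype table
#'
#' Long-format table with columns `individual_id`, `environment`, `trait`,
#' `value`. At most one record per (individual, environment, trait).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Construct/validate a phenotype table
#'
#' @param df data.frame with columns `individual_id`, `environment`,
#'   `trait`, `value`.
#' @return The validated data.frame with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  need <- c("individual_id", "environment", "trait", "value")
  if (!all(need %in% colnames(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df$individual_id <- as.character(df$individual_id)
  df$environment <- as.character(df$environment)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  key <- paste(df$individual_id, df$environment, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual, environment, trait) records")
  }
  class(df) <- unique(c("phenotype_table", class(df)))
  df
}

#' Write a phenotype table
#' @param phenos a [phenotype_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_phenotypes <- function(phenos, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(phenos), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a family membership table (columns individual_id, family_id)
#' @param path file path.
#' @return named character vector mapping individual id to family id.
#' @export
read_families <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("individual_id", "family_id") %in% colnames(df))) {
    stop("family table must have columns individual_id, family_id")
  }
  stats::setNames(as.character(df$family_id), as.character(df$individual_id))
}

#' Remove markers with too many missing calls
#'
#' Markers whose missing fraction strictly exceeds `max_missing` are removed
#' (a marker at exactly the threshold is kept); survivor order is preserved.
#'
#' @param panel a [genotype_panel()].
#' @param max_missing maximum tolerated missing fraction, default 0.5.
#' @return Filtered `genotype_panel`.
#' @export
filter_missing <- function(panel, max_missing = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"),
            max_missing >= 0, max_missing <= 1)
  miss_frac <- colMeans(is.na(panel$calls))
  keep <- miss_frac <= max_missing
  if (!any(keep)) stop("all markers removed by missing-rate filter")
  genotype_panel(panel$calls[, keep, drop = FALSE],
                 individual_ids = panel$individual_ids,
                 marker_ids = panel$marker_ids[keep],
                 env_of = panel$env_of, family_of = panel$family_of)
}

#' Impute missing calls by the marker mean
#'
#' Each missing call is replaced by the mean of the observed dosages of that
#' marker, a real number in \[0, 2\]. Observed calls are unchanged; imputed
#' dosages are not rounded.
#'
#' @param panel a [genotype_panel()].
#' @return Imputed `genotype_panel` with no missing entries.
#' @export
impute_marker_mean <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0L)) {
    stop("fully missing marker(s): ",
         paste(panel$marker_ids[n_obs == 0L], collapse = ", "),
         " (run filter_missing first)")
  }
  mu <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls))
  if (length(idx)) {
    calls[idx] <- mu[((idx - 1L) %/% nrow(calls)) + 1L]
  }
  genotype_panel(calls, individual_ids = panel$individual_ids,
                 marker_ids = panel$marker_ids,
                 env_of = panel$env_of, family_of = panel$family_of)
}

#' Minor allele frequencies of a panel
#'
#' `MAF_l = min(f_l, 1 - f_l)` with `f_l` the mean dosage of marker `l`
#' divided by 2. The panel should be imputed first; imputed fractional
#' dosages enter the mean.
#'
#' @param panel a [genotype_panel()] (no missing calls expected).
#' @return Named numeric vector of per-marker MAF in \[0, 0.5\].
#' @export
compute_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  f <- colMeans(panel$calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}
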