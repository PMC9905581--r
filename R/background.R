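#' Background genetic relationship matrix over records
#'
#' Builds the record-level matrix for the background genetic effect that is
#' not explained by the markers. In `identity` mode the matrix is the
#' identity (cross-environment background covariances are fixed at zero),
#' appropriate when no pedigree information is available. In `half_sib`
#' mode, two distinct records of individuals from the same family (within
#' or across environments) get the expected half-sib additive relatedness
#' 0.25, the diagonal is 1, and everything else is 0.
#'
#' @param records data.frame with columns `individual_id`, `environment`
#'   (e.g. a [phenotype_table()] restricted to one trait), one row per
#'   record.
#' @param families named character vector individual id -> family id
#'   (required in `half_sib` mode, must cover every record).
#' @param mode `"identity"` or `"half_sib"`.
#' @return Object of class `background_matrix`: `full` (n x n), `mode`,
#'   `records`.
#' @export
build_background <- function(records, families = NULL,
                             mode = c("identity", "half_sib")) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  stopifnot(all(c("individual_id", "environment") %in% colnames(records)))
  ids <- as.character(records$individual_id)
  n <- length(ids)
  if (mode == "identity") {
    B <- diag(n)
    fam <- NULL
  } else {
    if (is.null(families)) stop("half_sib mode requires a family map")
    fam <- families[ids]
    if (anyNA(fam)) {
      stop("missing family label for individual(s): ",
           paste(unique(ids[is.na(fam)]), collapse = ", "))
    }
    same_fam <- outer(fam, fam, "==")
    B <- ifelse(same_fam, 0.25, 0)
    diag(B) <- 1
  }
  structure(
    list(full = B, mode = mode,
         records = data.frame(individual_id = ids,
                              environment = as.character(records$environment),
                              stringsAsFactors = FALSE),
         family_of = fam),
    class = "background_matrix"
  )
}

#' @export
print.background_matrix <- function(x, ...) {
  cat("Background matrix (", x$mode, "): ", nrow(x$full), " records\n",
      sep = "")
  invisible(x)
}
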