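# Internal helpers shared across modules.

#' Convert a counts tibble (gene_id + sample columns) to an integer matrix
#'
#' @param counts data frame whose first column holds gene identifiers and
#'   whose remaining columns hold nonnegative counts.
#' @return numeric matrix with gene identifiers as rownames.
#' @keywords internal
#' @noRd
as_count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  id_col <- names(counts)[1]
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene identifiers in column '", id_col, "': ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric")
  if (anyNA(m) || any(!is.finite(m))) stop("counts must be finite and non-missing")
  if (any(m < 0)) stop("counts must be nonnegative")
  rownames(m) <- ids
  m
}

#' @noRd
counts_to_tibble <- function(m, id_name = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), out)
  out
}

# log(sum(exp(x))) without overflow; -Inf for empty input
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
check_samples <- function(samples, need = c("sample", "condition")) {
  stopifnot(is.data.frame(samples))
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample)) stop("duplicated sample names in sample sheet")
  invisible(samples)
}

# Validate that the sample sheet covers exactly the count columns, and
# return the sheet reordered to the column order of the matrix.
#' @noRd
align_samples <- function(m, samples) {
  check_samples(samples)
  cols <- colnames(m)
  if (!setequal(cols, samples$sample)) {
    stop("sample sheet and count columns disagree; missing from sheet: ",
         paste(utils::head(setdiff(cols, samples$sample), 3), collapse = ", "),
         "; missing from counts: ",
         paste(utils::head(setdiff(samples$sample, cols), 3), collapse = ", "))
  }
  samples[match(cols, samples$sample), , drop = FALSE]
}
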