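#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]. Missing values are
#' propagated and excluded from the number of tests `m`.
#'
#' @param pvalues numeric vector of P-values in `[0, 1]` (NA allowed).
#' @return vector of BH-adjusted P-values (q-values), same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("P-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Flag differentially expressed genes by the fold-change / FDR rule
#'
#' A gene is called DE when its fold change exceeds `fc_threshold`
#' (strictly, i.e. `|log2fc| > log2(fc_threshold)`) and its FDR is
#' strictly below `fdr_threshold`.
#'
#' @param results data frame with columns `log2fc` and `fdr`.
#' @param fc_threshold fold-change cutoff on the natural scale (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return the input as a tibble with a logical `is_de` column.
#' @export
call_de <- function(results, fc_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(results), all(c("log2fc", "fdr") %in% names(results)))
  dplyr::mutate(tibble::as_tibble(results),
                is_de = !is.na(.data$fdr) &
                  abs(.data$log2fc) > log2(fc_threshold) &
                  .data$fdr < fdr_threshold)
}

# Cell-means design over a condition factor; columns named by level.
#' @noRd
cell_means_design <- function(condition, levels = NULL) {
  if (is.null(levels)) levels <- unique(condition)
  miss <- setdiff(condition, levels)
  if (length(miss)) stop("condition(s) not in declared levels: ",
                         paste(unique(miss), collapse = ", "))
  f <- factor(condition, levels = levels)
  X <- stats::model.matrix(~ 0 + f)
  colnames(X) <- levels
  X
}

# Parse "8C_0h-28C" into a +1/-1 contrast over design columns.
#' @noRd
parse_contrast <- function(contrast, level_names) {
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("contrast must be of the form 'levelA-levelB'")
  miss <- setdiff(parts, level_names)
  if (length(miss)) stop("contrast level(s) not in the design: ",
                         paste(miss, collapse = ", "))
  v <- stats::setNames(rep(0, length(level_names)), level_names)
  v[parts[1]] <- 1
  v[parts[2]] <- -1
  v
}

#' Within-species differential expression between two conditions
#'
#' Fits a negative-binomial GLM with a cell-means design over the
#' condition factor and tests a single `condition - control` contrast by
#' likelihood-ratio test: TMM effective library sizes as offsets, common
#' (or tagwise) Cox-Reid dispersion, BH adjustment, and the strict
#' fold-change/FDR calling rule.
#'
#' Genes with all-zero counts are excluded from testing and from the
#' number of tests used by the BH adjustment; they are returned with NA
#' statistics.
#'
#' @param counts count data frame (first column gene ids).
#' @param samples sample sheet with columns `sample`, `condition` (and
#'   optionally `species`, `replicate`, `library_size`).
#' @param contrast character like `"8C_0h-28C"` naming two condition
#'   levels.
#' @param species optional species label to subset the sample sheet by
#'   its `species` column.
#' @param fc,fdr calling thresholds (fold change > `fc`, FDR < `fdr`).
#' @param dispersion optional dispersion (scalar, per-gene vector or
#'   [estimate_dispersion()] result); estimated (common) when NULL.
#' @param dispersion_method passed to [estimate_dispersion()] when
#'   `dispersion` is NULL.
#' @return tibble of class `xdg_de`: `gene_id`, `log2fc`, `pvalue`,
#'   `fdr`, `is_de`; the dispersion used and the contrast are attached as
#'   attributes.
#' @export
de_test <- function(counts, samples, contrast, species = NULL,
                    fc = 2, fdr = 0.05, dispersion = NULL,
                    dispersion_method = "common") {
  m <- as_count_matrix(counts)
  check_samples(samples)
  if (!is.null(species)) {
    # the sheet may cover both species; keep the requested one and the
    # count columns that belong to it
    if (!"species" %in% names(samples)) stop("sample sheet has no 'species' column")
    samples <- samples[samples$species == species, , drop = FALSE]
    if (nrow(samples) == 0) stop("no samples for species '", species, "'")
    miss <- setdiff(samples$sample, colnames(m))
    if (length(miss)) stop("sample(s) missing from the counts: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    m <- m[, samples$sample, drop = FALSE]
  } else {
    samples <- align_samples(m, samples)
  }
  levels <- unique(samples$condition)
  X <- cell_means_design(samples$condition, levels)
  nf <- tmm_normalize(counts_to_tibble(m), samples)
  offsets <- log(nf$effective_lib_size)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(m, X, offsets, method = dispersion_method)
  }
  phi <- dispersion_vector(dispersion, nrow(m))
  cvec <- parse_contrast(contrast, colnames(X))
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    if (all(y == 0)) return(list(log2fc = NA_real_, pvalue = NA_real_))
    lt <- lrt_contrast(y, X, cvec, offsets, phi[i])
    list(log2fc = lt$log2fc, pvalue = lt$pvalue)
  })
  out <- tibble::tibble(
    gene_id = rownames(m),
    log2fc = purrr::map_dbl(res, "log2fc"),
    pvalue = purrr::map_dbl(res, "pvalue"))
  out$fdr <- bh_adjust(out$pvalue)
  out <- call_de(out, fc_threshold = fc, fdr_threshold = fdr)
  attr(out, "contrast") <- contrast
  attr(out, "dispersion") <- dispersion
  class(out) <- c("xdg_de", class(out))
  out
}
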