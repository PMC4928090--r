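#' Replicate consistency: mean pairwise Pearson correlation
#'
#' Computes, within each (species x) condition, the mean pairwise
#' Pearson correlation of replicate expression profiles on the
#' `log2(CPM + 1)` scale. Conditions with a single replicate are skipped
#' with a warning.
#'
#' @param counts count data frame (first column gene ids).
#' @param samples sample sheet with columns `sample`, `condition` and
#'   optionally `species`.
#' @return tibble of class `xdg_qc`: (`species`,) `condition`,
#'   `n_replicates`, `mean_pearson`; the overall mean is attached as the
#'   `"overall"` attribute.
#' @export
qc_replicate_correlation <- function(counts, samples) {
  m <- as_count_matrix(counts)
  samples <- align_samples(m, samples)
  cpm <- t(t(m) / pmax(colSums(m), 1)) * 1e6
  lcpm <- log2(cpm + 1)
  grp_cols <- intersect(c("species", "condition"), names(samples))
  key <- do.call(paste, c(samples[grp_cols], sep = "\r"))
  out <- purrr::map_dfr(unique(key), function(k) {
    idx <- which(key == k)
    info <- samples[idx[1], grp_cols, drop = FALSE]
    if (length(idx) < 2) {
      warning("condition ", gsub("\r", ":", k),
              " has a single replicate; skipped", call. = FALSE)
      return(dplyr::bind_cols(info, tibble::tibble(
        n_replicates = length(idx), mean_pearson = NA_real_)))
    }
    cc <- stats::cor(lcpm[, idx, drop = FALSE], method = "pearson")
    dplyr::bind_cols(info, tibble::tibble(
      n_replicates = length(idx),
      mean_pearson = mean(cc[upper.tri(cc)])))
  })
  attr(out, "overall") <- mean(out$mean_pearson, na.rm = TRUE)
  class(out) <- c("xdg_qc", class(out))
  out
}
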