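#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' method: for each library against a reference library, gene-wise log2
#' expression ratios (M) and average log2 abundances (A) are formed from
#' library-size-scaled counts, the extremes of both are trimmed, and the
#' remaining M values are averaged with inverse-variance (delta-method)
#' weights. Factors are rescaled so their geometric mean is 1; the
#' effective library size of a sample is `library size x factor`.
#'
#' The reference sample is the one whose upper-quartile-scaled expression
#' is closest to the mean across samples. Genes with a zero count in
#' either the test or reference library are ignored for that pair.
#'
#' @param counts data frame: first column gene ids, remaining columns
#'   nonnegative counts (one per sample).
#' @param samples optional sample sheet (columns `sample`, ...). If it has
#'   a `library_size` column, those sizes override column sums.
#' @param trim_m fraction trimmed from each tail of the M values (default
#'   0.30).
#' @param trim_a fraction trimmed from each tail of the A values (default
#'   0.05).
#' @return a tibble with columns `sample`, `library_size`, `norm_factor`,
#'   `effective_lib_size`.
#' @examples
#' counts <- tibble::tibble(gene_id = paste0("g", 1:50),
#'                          s1 = rpois(50, 40), s2 = rpois(50, 40))
#' tmm_normalize(counts)
#' @export
tmm_normalize <- function(counts, samples = NULL, trim_m = 0.30, trim_a = 0.05) {
  m <- as_count_matrix(counts)
  lib <- colSums(m)
  if (!is.null(samples) && "library_size" %in% names(samples)) {
    samples <- align_samples(m, samples)
    lib <- samples$library_size
    names(lib) <- colnames(m)
  }
  zero <- lib <= 0 | colSums(m > 0) == 0
  if (any(zero)) {
    stop("sample(s) with no counts: ", paste(colnames(m)[zero], collapse = ", "))
  }
  # reference: upper quartile of scaled counts closest to the mean UQ
  uq <- apply(m, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) 1 else tmm_pair_factor(m[, k], m[, ref], lib[k], lib[ref],
                                         trim_m = trim_m, trim_a = trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample = colnames(m),
                 library_size = unname(lib),
                 norm_factor = unname(f),
                 effective_lib_size = unname(lib * f))
}

# One library against the reference: weighted trimmed mean of M values.
#' @noRd
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  m_val <- log2(p_o / p_r)
  a_val <- 0.5 * log2(p_o * p_r)
  # asymptotic (delta method) variance of M
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m_val) & is.finite(a_val) & w > 0
  m_val <- m_val[fin]; a_val <- a_val[fin]; w <- w[fin]
  n <- length(m_val)
  if (n == 0L) return(1)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m_val, ties.method = "first")
  ra_ <- rank(a_val, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  lf <- sum(m_val[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(lf) || abs(lf) < 1e-6) lf <- 0
  2^lf
}
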