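#' Upper-tail hypergeometric P-value for gene-set over-representation
#'
#' Probability of drawing at least `i` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `M`
#' carry the annotation:
#' `p = sum_{j=i}^{min(n,M)} C(M,j) C(N-M,n-j) / C(N,n)`.
#' The observed count is included in the tail. Computed by log-space
#' summation of the binomial-coefficient terms.
#'
#' @param N universe size (total genes).
#' @param n number of selected (e.g. divergently expressed) genes.
#' @param M number of genes annotated to the term.
#' @param i number of selected genes annotated to the term.
#' @return P-value in `(0, 1]`.
#' @examples
#' hypergeom_pvalue(N = 20, n = 5, M = 4, i = 2)
#' @export
hypergeom_pvalue <- function(N, n, M, i) {
  stopifnot(length(N) == 1, length(n) == 1, length(M) == 1, length(i) == 1)
  if (any(c(N, n, M, i) < 0) || n > N || M > N || i > min(n, M)) {
    stop("invalid query: need 0 <= i <= min(n, M), n <= N, M <= N")
  }
  j <- seq.int(max(i, max(0, n + M - N)), min(n, M))
  if (length(j) == 0L) return(1)
  lo <- lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)
  min(exp(logsumexp(lo)), 1)
}

#' Hypergeometric over-representation test across a gene-set collection
#'
#' For every term with at least one member in the universe, counts the
#' selected (divergent) members and computes the upper-tail
#' hypergeometric P-value. Terms are flagged enriched at raw
#' `p < alpha`; set `adjust = TRUE` to flag on BH-adjusted values
#' instead.
#'
#' @param annotation long-format data frame with columns `term_id`,
#'   `gene_id` and optionally `term_name`.
#' @param divergent character vector of selected gene ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all tested gene ids.
#' @param alpha enrichment threshold (default 0.05).
#' @param adjust if TRUE, also compute BH-adjusted P-values and flag on
#'   them.
#' @return tibble sorted by P-value: `term_id`, `term_name`, `n_universe`
#'   (M), `n_divergent` (i), `pvalue`, (`fdr`,) `enriched`.
#' @export
enrich_terms <- function(annotation, divergent, universe, alpha = 0.05,
                         adjust = FALSE) {
  stopifnot(is.data.frame(annotation),
            all(c("term_id", "gene_id") %in% names(annotation)))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  divergent <- unique(as.character(divergent))
  outside <- setdiff(divergent, universe)
  if (length(outside)) {
    stop("divergent gene(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  }
  ann <- dplyr::distinct(
    dplyr::filter(tibble::as_tibble(annotation), .data$gene_id %in% universe),
    .data$term_id, .data$gene_id,
    .keep_all = TRUE)
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  N <- length(universe)
  n <- length(divergent)
  per_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term_id),
    term_name = .data$term_name[1],
    n_universe = dplyr::n(),
    n_divergent = sum(.data$gene_id %in% divergent),
    .groups = "drop")
  per_term$pvalue <- purrr::map2_dbl(per_term$n_universe, per_term$n_divergent,
                                     function(M, i) hypergeom_pvalue(N, n, M, i))
  per_term <- dplyr::arrange(per_term, .data$pvalue, .data$term_id)
  if (adjust) {
    per_term$fdr <- bh_adjust(per_term$pvalue)
    per_term$enriched <- per_term$fdr < alpha
  } else {
    per_term$enriched <- per_term$pvalue < alpha
  }
  attr(per_term, "universe_size") <- N
  attr(per_term, "n_divergent_total") <- n
  class(per_term) <- c("xdg_enrichment", class(per_term))
  per_term
}
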