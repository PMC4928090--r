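# Cross-species TFBS enrichment: an ortholog pair "contains" a motif
# when the promoter of either species carries at least one hit, and the
# 2x2 table motif-presence x divergence is tested with Fisher's exact
# test. The reported odds ratio is the conditional maximum-likelihood
# estimate under the noncentral hypergeometric likelihood given both
# margins (the estimator standard exact-test implementations print),
# not the sample cross-product.

#' Two-sided Fisher's exact test with conditional-MLE odds ratio
#'
#' The two-sided P-value follows the point-probability rule: the sum of
#' the probabilities of all tables with the observed margins whose
#' hypergeometric point probability does not exceed that of the observed
#' table. The odds ratio solves the conditional score equation
#' `E_psi[a | margins] = a` by root finding on `log(psi)`; when the
#' observed count sits at the boundary of the conditional support the
#' estimate is 0 or `Inf`.
#'
#' @param a,b,c,d cell counts: `a` = divergent & present, `b` =
#'   divergent & absent, `c` = non-divergent & present, `d` =
#'   non-divergent & absent.
#' @param odds_ratio set FALSE to skip the (root-finding) odds-ratio
#'   estimate and return only the P-value.
#' @return tibble with one row: `pvalue`, `odds_ratio`, `or_defined`
#'   (FALSE when a zero margin makes the odds ratio undefined; the
#'   P-value is then 1 and `odds_ratio` is `NaN`).
#' @examples
#' fisher_exact(15, 9, 8, 33)  # p ~ 9.84e-4, OR ~ 6.63
#' @export
fisher_exact <- function(a, b, c, d, odds_ratio = TRUE) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("table cells must be nonnegative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(tibble::tibble(pvalue = 1, odds_ratio = NaN, or_defined = FALSE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- lp[support == a]
  pval <- min(sum(exp(lp[lp <= p_obs + 1e-7])), 1)
  if (!odds_ratio) {
    return(tibble::tibble(pvalue = pval, odds_ratio = NA_real_,
                          or_defined = NA))
  }
  # conditional MLE of the odds ratio: root of E_psi[X | margins] = a.
  # The root is bracketed on the psi scale below 1 and on the 1/psi scale
  # above 1 with uniroot's default tolerance, the convention of standard
  # exact-test implementations (whose printed estimates this reproduces).
  lw0 <- lchoose(r1, support) + lchoose(r2, c1 - support)
  cond_mean <- function(psi) {
    if (psi == 0) return(min(support))
    lw <- lw0 + support * log(psi)
    sum(support * exp(lw - logsumexp(lw)))
  }
  or <- if (a == min(support)) {
    0
  } else if (a == max(support)) {
    Inf
  } else {
    mu1 <- cond_mean(1)
    if (mu1 > a) {
      stats::uniroot(function(t) cond_mean(t) - a, c(0, 1))$root
    } else if (mu1 < a) {
      1 / stats::uniroot(function(t) cond_mean(1 / t) - a,
                         c(.Machine$double.eps, 1))$root
    } else 1
  }
  tibble::tibble(pvalue = pval, odds_ratio = or, or_defined = TRUE)
}

#' Motif-presence matrix over ortholog pairs (either-species rule)
#'
#' A pair is marked present for a motif when at least one hit falls in
#' the species-A promoter or in the species-B promoter. Pairs missing a
#' promoter in either species are excluded (reported via a message and
#' the `"excluded"` attribute).
#'
#' @param hits_a,hits_b hit tables from [scan_promoters()] (columns
#'   `gene_id`, `motif_id`) for the two species, computed with the same
#'   motif set and threshold.
#' @param map ortholog map (first two columns: species-A id, species-B
#'   id).
#' @param promoters_a,promoters_b optional promoter sets (data frames
#'   with `gene_id`) used to decide which pairs have both promoters;
#'   when NULL every mapped pair is kept.
#' @param motif_ids motifs to tabulate; defaults to all motifs seen in
#'   either hit table.
#' @return tibble: `pair_id` plus one logical column per motif.
#' @export
build_presence <- function(hits_a, hits_b, map,
                           promoters_a = NULL, promoters_b = NULL,
                           motif_ids = NULL) {
  ga <- as.character(map[[1]]); gb <- as.character(map[[2]])
  keep <- rep(TRUE, length(ga))
  if (!is.null(promoters_a)) keep <- keep & ga %in% promoters_a$gene_id
  if (!is.null(promoters_b)) keep <- keep & gb %in% promoters_b$gene_id
  if (any(!keep)) {
    message(sum(!keep), " pair(s) excluded for lack of a promoter in one species")
  }
  excluded <- paste(ga[!keep], gb[!keep], sep = "|")
  ga <- ga[keep]; gb <- gb[keep]
  if (is.null(motif_ids)) {
    motif_ids <- sort(unique(c(hits_a$motif_id, hits_b$motif_id)))
  }
  pres <- tibble::tibble(pair_id = paste(ga, gb, sep = "|"))
  for (m in motif_ids) {
    in_a <- ga %in% hits_a$gene_id[hits_a$motif_id == m]
    in_b <- gb %in% hits_b$gene_id[hits_b$motif_id == m]
    pres[[m]] <- in_a | in_b
  }
  attr(pres, "excluded") <- excluded
  pres
}

#' TFBS enrichment among divergently expressed ortholog pairs
#'
#' For every motif, builds the 2x2 table of motif presence against
#' divergence over the pairs in `scope` and applies [fisher_exact()].
#' Motifs are flagged at raw `p < alpha` (set `adjust = TRUE` for BH).
#'
#' @param presence presence matrix from [build_presence()].
#' @param divergent character vector of divergent pair ids.
#' @param scope pair ids delimiting the tested gene set (e.g. the
#'   members of one GO category); defaults to all rows of `presence`.
#' @param alpha flagging threshold (default 0.05).
#' @param adjust if TRUE, flag on BH-adjusted P-values.
#' @return tibble of class `xdg_tfbs`, sorted by P-value:
#'   `motif_id`, `present_divergent` (a), `absent_divergent` (b),
#'   `present_nondivergent` (c), `absent_nondivergent` (d),
#'   `odds_ratio`, `pvalue`, (`fdr`,) `enriched`.
#' @export
enrich_tfbs <- function(presence, divergent, scope = NULL, alpha = 0.05,
                        adjust = FALSE) {
  stopifnot(is.data.frame(presence), "pair_id" %in% names(presence))
  if (is.null(scope)) scope <- presence$pair_id
  scope <- unique(as.character(scope))
  if (length(scope) == 0L) stop("empty scope")
  missing_scope <- setdiff(scope, presence$pair_id)
  if (length(missing_scope)) {
    stop("scope pair(s) absent from the presence matrix: ",
         paste(utils::head(missing_scope, 3), collapse = ", "))
  }
  pres <- presence[presence$pair_id %in% scope, , drop = FALSE]
  is_div <- pres$pair_id %in% divergent
  motifs <- setdiff(names(pres), "pair_id")
  out <- purrr::map_dfr(motifs, function(m) {
    p <- pres[[m]]
    a <- sum(p & is_div); b <- sum(!p & is_div)
    cc <- sum(p & !is_div); d <- sum(!p & !is_div)
    ft <- fisher_exact(a, b, cc, d)
    tibble::tibble(motif_id = m,
                   present_divergent = a, absent_divergent = b,
                   present_nondivergent = cc, absent_nondivergent = d,
                   odds_ratio = ft$odds_ratio, pvalue = ft$pvalue)
  })
  out <- dplyr::arrange(out, .data$pvalue, .data$motif_id)
  if (adjust) {
    out$fdr <- bh_adjust(out$pvalue)
    out$enriched <- out$fdr < alpha
  } else {
    out$enriched <- out$pvalue < alpha
  }
  attr(out, "n_divergent") <- sum(is_div)
  attr(out, "n_scope") <- length(scope)
  class(out) <- c("xdg_tfbs", class(out))
  out
}

#' Flag apoptosis-related transcription factors by GO term keywords
#'
#' A transcription factor is apoptosis-related when at least one of its
#' GO term names contains the literal substring "apoptosis" or
#' "apoptotic" (case-insensitive). Terms such as "programmed cell death"
#' do not match: the rule is a literal keyword rule.
#'
#' @param go_annotations data frame with columns `gene_id`, `term_name`.
#' @param tf_ids character vector of transcription-factor gene ids (e.g.
#'   from a DNA-binding-domain catalog).
#' @return tibble: `gene_id`, `is_tf`, `is_apoptosis_related` (TRUE only
#'   for TFs), one row per gene appearing in either input.
#' @export
define_apoptosis_tfs <- function(go_annotations, tf_ids) {
  stopifnot(is.data.frame(go_annotations),
            all(c("gene_id", "term_name") %in% names(go_annotations)))
  tf_ids <- unique(as.character(tf_ids))
  hit <- grepl("apoptosis|apoptotic", go_annotations$term_name, ignore.case = TRUE)
  matched <- unique(go_annotations$gene_id[hit])
  genes <- union(tf_ids, unique(go_annotations$gene_id))
  tibble::tibble(gene_id = genes,
                 is_tf = genes %in% tf_ids,
                 is_apoptosis_related = genes %in% tf_ids & genes %in% matched)
}

#' Induced interaction subnetwork and query-node connectivity
#'
#' Builds the undirected graph induced by the query nodes plus any
#' declared intermediates on a user-supplied edge table, and reports the
#' fraction of query nodes falling in the largest connected component.
#' Query nodes absent from the edge list are kept as isolates.
#'
#' @param edges data frame with columns `source`, `target` and
#'   optionally `type` (e.g. physical / colocalization / genetic).
#' @param nodes character vector of query node ids.
#' @param intermediates additional node ids allowed to bridge the query
#'   nodes.
#' @return list of class `xdg_subnetwork`: `graph` (igraph),
#'   `membership` tibble (`node`, `is_query`, `component`),
#'   `connectivity` (fraction of query nodes in the largest component,
#'   counting query nodes only).
#' @export
extract_subnetwork <- function(edges, nodes, intermediates = NULL) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  nodes <- unique(as.character(nodes))
  allowed <- union(nodes, intermediates %||% character())
  e <- dplyr::filter(edges, .data$source %in% allowed, .data$target %in% allowed)
  verts <- union(allowed[allowed %in% c(e$source, e$target)], nodes)
  g <- igraph::graph_from_data_frame(e[, c("source", "target",
                                           intersect("type", names(e)))],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  memb <- tibble::tibble(node = names(comp$membership),
                         is_query = names(comp$membership) %in% nodes,
                         component = unname(comp$membership))
  # largest component by number of query nodes it contains
  per_comp <- table(memb$component[memb$is_query])
  connectivity <- if (length(per_comp)) max(per_comp) / length(nodes) else 0
  structure(list(graph = g, membership = memb,
                 connectivity = unname(connectivity)),
            class = "xdg_subnetwork")
}
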