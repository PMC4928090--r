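# broom-style tidiers, glance summaries, autoplot methods and printers
# for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @noRd
strip_xdg <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "xdg_")]
  for (a in c("dispersion", "contrast", "control", "timepoints", "overall",
              "universe_size", "n_divergent_total", "n_divergent", "n_scope",
              "dropped", "excluded")) {
    attr(x, a) <- NULL
  }
  x
}

#' @rdname call_divergent
#' @param x,object an `xdg_divergence` result.
#' @param ... unused.
#' @export
tidy.xdg_divergence <- function(x, ...) tibble::as_tibble(strip_xdg(x))

#' @rdname call_divergent
#' @export
glance.xdg_divergence <- function(x, ...) {
  per_tp <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$timepoint),
                             n_tested = sum(!is.na(.data$pvalue)),
                             n_divergent = sum(.data$is_divergent, na.rm = TRUE),
                             .groups = "drop")
  per_tp$n_union <- length(divergent_union(x))
  per_tp
}

#' @rdname call_divergent
#' @export
autoplot.xdg_divergence <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$pvalue), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$is_divergent)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~timepoint) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "interaction contrast (log2)", y = "-log10 FDR",
                  colour = "divergent") +
    ggplot2::theme_minimal()
}

#' @rdname de_test
#' @param x,object an `xdg_de` result.
#' @param ... unused.
#' @export
tidy.xdg_de <- function(x, ...) tibble::as_tibble(strip_xdg(x))

#' @rdname de_test
#' @export
glance.xdg_de <- function(x, ...) {
  disp <- attr(x, "dispersion")
  tibble::tibble(contrast = attr(x, "contrast") %||% NA_character_,
                 n_tested = sum(!is.na(x$pvalue)),
                 n_de = sum(x$is_de, na.rm = TRUE),
                 n_up = sum(x$is_de & x$log2fc > 0, na.rm = TRUE),
                 n_down = sum(x$is_de & x$log2fc < 0, na.rm = TRUE),
                 dispersion_common = if (inherits(disp, "xdg_dispersion"))
                   disp$common else NA_real_)
}

#' @rdname enrich_terms
#' @param x,object an `xdg_enrichment` result.
#' @param ... unused.
#' @export
tidy.xdg_enrichment <- function(x, ...) tibble::as_tibble(strip_xdg(x))

#' @rdname enrich_terms
#' @export
glance.xdg_enrichment <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x),
                 n_enriched = sum(x$enriched),
                 universe_size = attr(x, "universe_size") %||% NA_integer_,
                 n_divergent = attr(x, "n_divergent_total") %||% NA_integer_)
}

#' @rdname enrich_terms
#' @param n_top number of top terms to draw.
#' @export
autoplot.xdg_enrichment <- function(object, n_top = 15, ...) {
  df <- utils::head(tidy(object), n_top)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$pvalue), y = .data$term_name,
                                   fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "-log10 P", y = NULL, fill = "enriched") +
    ggplot2::theme_minimal()
}

#' @rdname enrich_tfbs
#' @param x,object an `xdg_tfbs` result.
#' @param ... unused.
#' @export
tidy.xdg_tfbs <- function(x, ...) tibble::as_tibble(strip_xdg(x))

#' @rdname enrich_tfbs
#' @export
glance.xdg_tfbs <- function(x, ...) {
  tibble::tibble(n_motifs = nrow(x),
                 n_enriched = sum(x$enriched),
                 n_scope = attr(x, "n_scope") %||% NA_integer_,
                 n_divergent = attr(x, "n_divergent") %||% NA_integer_)
}

#' @rdname enrich_tfbs
#' @export
autoplot.xdg_tfbs <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$odds_ratio) & df$odds_ratio > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$odds_ratio),
                                   y = -log10(.data$pvalue),
                                   colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 conditional-MLE odds ratio", y = "-log10 P",
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' @rdname qc_replicate_correlation
#' @param x,object an `xdg_qc` result.
#' @param ... unused.
#' @export
glance.xdg_qc <- function(x, ...) {
  tibble::tibble(n_conditions = nrow(x),
                 overall_mean_pearson = attr(x, "overall") %||% NA_real_)
}

#' @rdname qc_replicate_correlation
#' @export
autoplot.xdg_qc <- function(object, ...) {
  df <- tibble::as_tibble(strip_xdg(object))
  df$label <- if ("species" %in% names(df)) {
    paste(df$species, df$condition, sep = ":")
  } else df$condition
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean_pearson)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean pairwise Pearson r (log2 CPM+1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname extract_subnetwork
#' @param x an `xdg_subnetwork` result.
#' @param ... unused.
#' @export
glance.xdg_subnetwork <- function(x, ...) {
  tibble::tibble(n_nodes = igraph::vcount(x$graph),
                 n_edges = igraph::ecount(x$graph),
                 n_query = sum(x$membership$is_query),
                 connectivity = x$connectivity)
}

#' @export
print.xdg_pwm <- function(x, ...) {
  cat("PWM", x$motif_id %||% "", "length", x$length,
      "| background", paste(round(x$background, 3), collapse = "/"), "\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' @export
print.xdg_dispersion <- function(x, ...) {
  cat("NB dispersion (", x$method, "): common =", signif(x$common, 4), "\n")
  if (x$method == "tagwise") {
    cat("tagwise range:",
        paste(signif(range(x$tagwise, na.rm = TRUE), 4), collapse = " - "), "\n")
  }
  invisible(x)
}

#' @export
print.xdg_subnetwork <- function(x, ...) {
  cat("Induced subnetwork:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges;",
      sprintf("%.0f%%", 100 * x$connectivity),
      "of query nodes in the largest component\n")
  invisible(x)
}
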