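# Cross-species divergence: a combined species:condition cell-means
# design, and difference-of-differences contrasts
#   (B:timepoint - B:control) - (A:timepoint - A:control)
# on ortholog pairs. A positive contrast means a larger response to the
# challenge in species B. Normalizing each species to its own control is
# achieved entirely by the contrast; counts are never pre-divided.

#' Merge two species' count matrices over a one-to-one ortholog map
#'
#' Keeps the pairs whose genes are present in both matrices and pass the
#' expression filter (at least `min_count` in at least `min_samples`
#' samples, in each species), and joins the two matrices row-wise on the
#' pair. Sample names must be unique across species.
#'
#' @param counts_a,counts_b count data frames (first column gene ids).
#' @param map ortholog map: data frame whose first two columns are the
#'   species-A and species-B gene ids; strictly one-to-one.
#' @param min_count,min_samples expression filter: a gene is "expressed"
#'   when `>= min_count` in `>= min_samples` of its species' samples.
#' @return tibble with columns `pair_id`, `gene_a`, `gene_b`, then all
#'   species-A and species-B sample columns. Dropped pairs are reported
#'   via a message and recorded in the `"dropped"` attribute.
#' @export
merge_ortholog_counts <- function(counts_a, counts_b, map,
                                  min_count = 1, min_samples = 3) {
  stopifnot(is.data.frame(map), ncol(map) >= 2)
  ga <- as.character(map[[1]])
  gb <- as.character(map[[2]])
  dup <- c(ga[duplicated(ga)], gb[duplicated(gb)])
  if (length(dup)) stop("ortholog map is not one-to-one; duplicated id(s): ",
                        paste(utils::head(unique(dup), 3), collapse = ", "))
  ma <- as_count_matrix(counts_a)
  mb <- as_count_matrix(counts_b)
  if (any(colnames(ma) %in% colnames(mb))) {
    stop("sample names must be unique across the two species")
  }
  in_both <- ga %in% rownames(ma) & gb %in% rownames(mb)
  expressed <- function(m, ids, present) {
    ok <- rep(FALSE, length(ids))
    ok[present] <- rowSums(m[ids[present], , drop = FALSE] >= min_count) >= min_samples
    ok
  }
  keep <- in_both &
    expressed(ma, ga, ga %in% rownames(ma)) &
    expressed(mb, gb, gb %in% rownames(mb))
  dropped <- tibble::tibble(gene_a = ga[!keep], gene_b = gb[!keep],
                            reason = ifelse(in_both[!keep], "not expressed", "missing"))
  if (nrow(dropped)) {
    message(nrow(dropped), " ortholog pair(s) dropped (",
            sum(dropped$reason == "missing"), " missing, ",
            sum(dropped$reason == "not expressed"), " below the expression filter)")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(pair_id = paste(ga[keep], gb[keep], sep = "|"),
                   gene_a = ga[keep], gene_b = gb[keep]),
    tibble::as_tibble(ma[ga[keep], , drop = FALSE]),
    tibble::as_tibble(mb[gb[keep], , drop = FALSE]))
  attr(out, "dropped") <- dropped
  out
}

#' Difference-of-differences contrast for one timepoint
#'
#' Builds the interaction contrast
#' `(B:timepoint - B:control) - (A:timepoint - A:control)` on a
#' cell-means design whose levels are named `species:condition`.
#' Entries sum to zero; a positive value means a larger response in
#' species B.
#'
#' @param level_names design column names, `"species:condition"`.
#' @param timepoint condition label to compare against the control.
#' @param control control condition label.
#' @param species the two species labels, `c(A, B)`.
#' @return named numeric contrast vector over `level_names`.
#' @examples
#' lv <- c("A:28C", "A:8C_0h", "B:28C", "B:8C_0h")
#' divergence_contrast(lv, "8C_0h", "28C")
#' @export
divergence_contrast <- function(level_names, timepoint, control = "28C",
                                species = c("A", "B")) {
  need <- c(paste(species[2], timepoint, sep = ":"),
            paste(species[2], control, sep = ":"),
            paste(species[1], timepoint, sep = ":"),
            paste(species[1], control, sep = ":"))
  miss <- setdiff(need, level_names)
  if (length(miss)) stop("design level(s) missing: ", paste(miss, collapse = ", "))
  v <- stats::setNames(rep(0, length(level_names)), level_names)
  v[need] <- c(1, -1, -1, 1)
  v
}

#' Call divergently expressed ortholog pairs per timepoint
#'
#' Fits one NB-GLM per ortholog pair over the combined
#' `species:condition` cell-means design (both species in one model,
#' each sample offset by its own species' TMM effective library size),
#' then tests the difference-of-differences contrast at every requested
#' timepoint by likelihood-ratio test. BH adjustment is applied within
#' each timepoint (the number of tests is the number of tested pairs);
#' pairs are flagged divergent by the strict `|log2fc| > log2(fc)` and
#' `fdr < fdr` rule.
#'
#' @param joint_counts output of [merge_ortholog_counts()] (columns
#'   `pair_id`, `gene_a`, `gene_b`, then samples), or any count frame
#'   whose first column identifies the pair.
#' @param samples sample sheet covering all columns: `sample`, `species`,
#'   `condition` (and optionally `replicate`, `library_size`).
#' @param timepoints condition labels to contrast against `control`.
#' @param control control condition label (default `"28C"`).
#' @param fc,fdr calling thresholds (fold change > `fc`, FDR < `fdr`).
#' @param dispersion optional dispersion; estimated on the combined
#'   design (common, or `dispersion_method = "tagwise"`) when NULL.
#' @param dispersion_method passed to [estimate_dispersion()].
#' @param species_order the two species labels as `c(A, B)`; a positive
#'   contrast means a larger response in the second. Defaults to the
#'   sorted labels of the sample sheet, so relabeling the species flips
#'   every contrast sign exactly.
#' @return tibble of class `xdg_divergence`: `pair_id`, `timepoint`,
#'   `log2fc`, `pvalue`, `fdr`, `is_divergent`, one row per pair x
#'   timepoint. `gene_a`/`gene_b` are carried through when present.
#' @export
call_divergent <- function(joint_counts, samples, timepoints, control = "28C",
                           fc = 2, fdr = 0.05, dispersion = NULL,
                           dispersion_method = "common", species_order = NULL) {
  stopifnot(is.data.frame(joint_counts))
  meta_cols <- intersect(c("pair_id", "gene_a", "gene_b"), names(joint_counts))
  if (!length(meta_cols)) meta_cols <- names(joint_counts)[1]
  meta <- joint_counts[, meta_cols, drop = FALSE]
  m <- as_count_matrix(joint_counts[, c(meta_cols[1],
                                        setdiff(names(joint_counts), meta_cols))])
  samples <- align_samples(m, samples)
  check_samples(samples, c("sample", "species", "condition"))
  sp <- species_order %||% sort(unique(samples$species))
  if (length(sp) != 2 || !setequal(sp, unique(samples$species))) {
    stop("exactly two species are required, found: ",
         paste(unique(samples$species), collapse = ", "))
  }
  bad_tp <- setdiff(c(control, timepoints), unique(samples$condition))
  if (length(bad_tp)) stop("condition(s) not present in the design: ",
                           paste(bad_tp, collapse = ", "))
  level <- paste(samples$species, samples$condition, sep = ":")
  X <- cell_means_design(level, unique(level))
  # per-species TMM offsets: each sample keeps its own species' scaling
  offsets <- rep(NA_real_, ncol(m))
  for (s in sp) {
    idx <- samples$species == s
    nf <- tmm_normalize(counts_to_tibble(m[, idx, drop = FALSE]),
                        samples[idx, , drop = FALSE])
    offsets[idx] <- log(nf$effective_lib_size)
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(m, X, offsets, method = dispersion_method)
  }
  phi <- dispersion_vector(dispersion, nrow(m))
  group <- cellmeans_group(X)
  phi_u <- unique(phi)
  common_phi <- length(phi_u) == 1L
  # full fits: vectorized across pairs when the dispersion is shared
  if (common_phi) {
    full <- fit_cellmeans_matrix(m, group, offsets, phi_u)
    beta_full <- full$beta
    dev_full <- vapply(seq_len(nrow(m)), function(i)
      nb_deviance(m[i, ], full$mu[i, ], phi_u), numeric(1))
  }
  res <- purrr::map_dfr(timepoints, function(tp) {
    cvec <- divergence_contrast(colnames(X), tp, control, species = sp)
    stats_tp <- purrr::map(seq_len(nrow(m)), function(i) {
      y <- m[i, ]
      if (all(y == 0)) return(list(log2fc = NA_real_, pvalue = NA_real_))
      if (common_phi) {
        ff <- list(beta = beta_full[i, ], mu = NULL, deviance = dev_full[i],
                   all_zero = FALSE, dispersion = phi_u)
        class(ff) <- "xdg_nbfit"
        lt <- lrt_contrast(y, X, cvec, offsets, phi_u, fit_full = ff)
      } else {
        lt <- lrt_contrast(y, X, cvec, offsets, phi[i])
      }
      list(log2fc = lt$log2fc, pvalue = lt$pvalue)
    })
    out <- dplyr::bind_cols(meta, tibble::tibble(
      timepoint = tp,
      log2fc = purrr::map_dbl(stats_tp, "log2fc"),
      pvalue = purrr::map_dbl(stats_tp, "pvalue")))
    out$fdr <- bh_adjust(out$pvalue)
    out
  })
  res <- call_de(res, fc_threshold = fc, fdr_threshold = fdr)
  res <- dplyr::rename(res, is_divergent = "is_de")
  attr(res, "control") <- control
  attr(res, "timepoints") <- timepoints
  attr(res, "dispersion") <- dispersion
  class(res) <- c("xdg_divergence", class(res))
  res
}

#' Union of divergent pairs across timepoints
#'
#' @param divergence result of [call_divergent()].
#' @return character vector of pair ids divergent at one or more
#'   timepoints (the logical OR of the per-timepoint flags).
#' @export
divergent_union <- function(divergence) {
  stopifnot(is.data.frame(divergence),
            all(c("pair_id", "is_divergent") %in% names(divergence)))
  sort(unique(divergence$pair_id[divergence$is_divergent %in% TRUE]))
}
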