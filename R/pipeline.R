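# End-to-end orchestration: counts -> divergence -> gene-set enrichment
# -> promoter scanning -> TFBS enrichment (-> subnetwork), with a JSON
# run manifest. Either all inputs are files, or `simulate = TRUE`
# generates a synthetic bundle first, writes it to disk, and runs the
# pipeline from those files.

#' Pipeline configuration
#'
#' Collects thresholds, input paths and the seed. In simulation mode
#' (`simulate = TRUE`) input paths are ignored and a synthetic bundle is
#' generated under `out_dir/inputs` before the run.
#'
#' @param out_dir output directory.
#' @param control control condition label.
#' @param timepoints condition labels tested against the control.
#' @param fc,fdr divergence calling thresholds.
#' @param go_alpha gene-set enrichment threshold.
#' @param motif_p motif scan P-value threshold.
#' @param promoter_len promoter length.
#' @param seed run seed.
#' @param simulate generate synthetic inputs instead of reading files.
#' @param counts_a,counts_b,samples,orthologs,annotation,promoters_a,promoters_b,motifs,edges,scope
#'   input file paths (TSV / FASTA / JASPAR); optional stages are
#'   skipped when their inputs are NULL.
#' @param sim simulation options passed to [sim_config()] (list), used
#'   when `simulate = TRUE`.
#' @return list of class `xdg_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, control = "28C",
                            timepoints = c("8C_0h", "8C_6h", "8C_12h"),
                            fc = 2, fdr = 0.05, go_alpha = 0.05,
                            motif_p = 1e-4, promoter_len = 1000,
                            seed = 1L, simulate = FALSE,
                            counts_a = NULL, counts_b = NULL, samples = NULL,
                            orthologs = NULL, annotation = NULL,
                            promoters_a = NULL, promoters_b = NULL,
                            motifs = NULL, edges = NULL, scope = NULL,
                            sim = list()) {
  stopifnot(fc > 1, fdr > 0, fdr < 1, go_alpha > 0, go_alpha < 1,
            motif_p > 0, motif_p < 1, promoter_len >= 1)
  cfg <- as.list(environment())
  if (!simulate) {
    required <- c("counts_a", "counts_b", "samples", "orthologs")
    for (f in required) {
      if (is.null(cfg[[f]])) stop("input '", f, "' is required unless simulate = TRUE")
      if (!file.exists(cfg[[f]])) stop("input '", f, "' not found: ", cfg[[f]])
    }
    for (f in c("annotation", "promoters_a", "promoters_b", "motifs",
                "edges", "scope")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop("input '", f, "' not found: ", cfg[[f]])
      }
    }
  }
  structure(cfg, class = "xdg_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return list of class `xdg_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @noRd
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# default JASPAR-style PFM used when simulating promoters: a strong
# 10-column site (written to inputs/motifs.jaspar by the simulate step)
#' @noRd
default_sim_pfm <- function() {
  pfm <- rbind(A = c(90,  2,  2, 90,  2,  2, 90,  2,  2, 90),
               C = c( 4,  2, 90,  2,  2, 90,  4,  2, 90,  2),
               G = c( 4, 90,  4,  4, 90,  4,  4, 90,  4,  4),
               T = c( 2,  6,  4,  4,  6,  4,  2, 96,  4,  4))
  pfm
}

#' @noRd
write_jaspar <- function(motifs, path) {
  lines <- unlist(purrr::pmap(motifs, function(motif_id, name, pfm) {
    c(paste0(">", motif_id, " ", name),
      vapply(1:4, function(r) paste0(DNA_BASES[r], " [ ",
                                     paste(pfm[r, ], collapse = " "), " ]"),
             character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full cross-species divergence pipeline
#'
#' Stages: replicate QC, ortholog merging and divergence calling,
#' gene-set enrichment of the divergent union, promoter scanning of both
#' species, either-species TFBS enrichment, and (when an edge list is
#' supplied) subnetwork extraction. All results are written as TSV under
#' the output directory together with a deterministic JSON run manifest
#' (`manifest.json`) recording thresholds, the seed and row counts.
#'
#' @param config an [pipeline_config()] object, or a YAML path.
#' @return invisibly, a list with the results of every stage and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "xdg_pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- config[c("counts_a", "counts_b", "samples", "orthologs",
                    "annotation", "promoters_a", "promoters_b", "motifs",
                    "edges", "scope")]
  if (isTRUE(config$simulate)) {
    paths <- run_stage("simulate", {
      in_dir <- file.path(out_dir, "inputs")
      dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
      sim_args <- utils::modifyList(
        list(seed = config$seed, n_pairs = 300,
             conditions = c(config$control, config$timepoints),
             promoter_length = config$promoter_len),
        config$sim)
      scfg <- do.call(sim_config, sim_args)
      bundle <- simulate_counts(scfg)
      motifs_tbl <- tibble::tibble(motif_id = "M0001", name = "synthetic_site",
                                   pfm = list(default_sim_pfm()))
      prom <- simulate_promoters(scfg, bundle$truth, motifs_tbl$pfm[[1]],
                                 motif_id = "M0001")
      go <- simulate_go(scfg, bundle$truth)
      p <- list(counts_a = file.path(in_dir, "counts_a.tsv"),
                counts_b = file.path(in_dir, "counts_b.tsv"),
                samples = file.path(in_dir, "samples.tsv"),
                orthologs = file.path(in_dir, "orthologs.tsv"),
                annotation = file.path(in_dir, "annotation.tsv"),
                promoters_a = file.path(in_dir, "promoters_a.fa"),
                promoters_b = file.path(in_dir, "promoters_b.fa"),
                motifs = file.path(in_dir, "motifs.jaspar"),
                edges = NULL, scope = NULL)
      write_result_tsv(bundle$counts_a, p$counts_a)
      write_result_tsv(bundle$counts_b, p$counts_b)
      write_result_tsv(bundle$samples, p$samples)
      write_result_tsv(bundle$map, p$orthologs)
      write_result_tsv(go$annotation, p$annotation)
      write_promoters(prom$promoters_a, p$promoters_a)
      write_promoters(prom$promoters_b, p$promoters_b)
      write_jaspar(motifs_tbl, p$motifs)
      write_result_tsv(bundle$truth, file.path(in_dir, "truth_pairs.tsv"))
      write_result_tsv(prom$placements, file.path(in_dir, "truth_placements.tsv"))
      writeLines(go$planted_terms, file.path(in_dir, "truth_terms.txt"))
      p
    })
  }
  counts_a <- run_stage("read counts_a", read_counts(paths$counts_a))
  counts_b <- run_stage("read counts_b", read_counts(paths$counts_b))
  samples <- run_stage("read samples", read_sample_sheet(paths$samples))
  map <- run_stage("read orthologs", read_ortholog_map(paths$orthologs))

  sp <- unique(samples$species)
  qc <- run_stage("qc", {
    dplyr::bind_rows(
      qc_replicate_correlation(counts_a, samples[samples$species == sp[1], ]),
      qc_replicate_correlation(counts_b, samples[samples$species == sp[2], ]))
  })
  write_result_tsv(qc, file.path(out_dir, "qc_replicates.tsv"))

  joint <- run_stage("merge orthologs",
                     merge_ortholog_counts(counts_a, counts_b, map))
  divergence <- run_stage("divergence", {
    call_divergent(joint, samples, timepoints = config$timepoints,
                   control = config$control, fc = config$fc, fdr = config$fdr)
  })
  write_result_tsv(divergence, file.path(out_dir, "divergence.tsv"))
  div_union <- divergent_union(divergence)

  go_res <- NULL
  if (!is.null(paths$annotation)) {
    go_res <- run_stage("go enrichment", {
      ann <- read_annotation(paths$annotation)
      enrich_terms(ann, divergent = div_union, universe = joint$pair_id,
                   alpha = config$go_alpha)
    })
    write_result_tsv(go_res, file.path(out_dir, "go_enrichment.tsv"))
  }

  tfbs <- NULL; hits_a <- NULL; hits_b <- NULL
  if (!is.null(paths$promoters_a) && !is.null(paths$motifs)) {
    scan <- run_stage("promoter scan", {
      pa <- read_promoters(paths$promoters_a)
      pb <- read_promoters(paths$promoters_b)
      motifs <- read_jaspar(paths$motifs)
      bg <- promoter_background(dplyr::bind_rows(pa, pb))
      list(pa = pa, pb = pb, motifs = motifs,
           hits_a = scan_promoters(pa, motifs, threshold = config$motif_p,
                                   background = bg),
           hits_b = scan_promoters(pb, motifs, threshold = config$motif_p,
                                   background = bg))
    })
    hits_a <- scan$hits_a; hits_b <- scan$hits_b
    write_result_tsv(hits_a, file.path(out_dir, "hits_a.tsv"))
    write_result_tsv(hits_b, file.path(out_dir, "hits_b.tsv"))
    tfbs <- run_stage("tfbs enrichment", {
      pres <- build_presence(hits_a, hits_b, map,
                             promoters_a = scan$pa, promoters_b = scan$pb,
                             motif_ids = scan$motifs$motif_id)
      scope <- if (!is.null(paths$scope)) readLines(paths$scope) else NULL
      enrich_tfbs(pres, divergent = div_union, scope = scope)
    })
    write_result_tsv(tfbs, file.path(out_dir, "tfbs_enrichment.tsv"))
  }

  subnet <- NULL
  if (!is.null(paths$edges)) {
    subnet <- run_stage("subnetwork", {
      edges <- readr::read_tsv(paths$edges, show_col_types = FALSE)
      extract_subnetwork(edges, nodes = div_union)
    })
    write_result_tsv(subnet$membership, file.path(out_dir, "subnetwork.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(fc = config$fc, fdr = config$fdr,
                      go_alpha = config$go_alpha, motif_p = config$motif_p,
                      promoter_len = config$promoter_len),
    control = config$control,
    timepoints = as.list(config$timepoints),
    n_samples = nrow(samples),
    n_ortholog_pairs_mapped = nrow(map),
    n_pairs_tested = nrow(joint),
    qc_mean_pearson = round(attr(qc, "overall"), 6),
    divergent_per_timepoint = as.list(stats::setNames(
      vapply(config$timepoints, function(tp)
        sum(divergence$is_divergent[divergence$timepoint == tp]), integer(1)),
      config$timepoints)),
    divergent_union = length(div_union),
    n_go_terms_tested = if (is.null(go_res)) NA else nrow(go_res),
    n_go_terms_enriched = if (is.null(go_res)) NA else sum(go_res$enriched),
    n_motif_hits = if (is.null(hits_a)) NA else nrow(hits_a) + nrow(hits_b),
    n_tfbs_enriched = if (is.null(tfbs)) NA else sum(tfbs$enriched),
    subnetwork_connectivity = if (is.null(subnet)) NA else subnet$connectivity)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(qc = qc, divergence = divergence, go = go_res,
                 hits_a = hits_a, hits_b = hits_b, tfbs = tfbs,
                 subnetwork = subnet, manifest = manifest,
                 paths = paths, out_dir = out_dir))
}
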