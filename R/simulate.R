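# Synthetic inputs with recorded ground truth. The generator emulates a
# two-species challenge time course: 2 species x {control + timepoints} x
# replicates NB counts with planted difference-of-differences effects,
# promoter sequences with planted motif occurrences, and gene-set
# annotations with planted enriched terms.
#
# One global seed expands into per-component seeds by a fixed counter
# (seed + 1 for counts, + 2 for promoters, + 3 for annotations), so
# adding a generator never perturbs the output of the existing ones.

#' Simulation configuration
#'
#' Defaults emulate a two-species cold-exposure design: control 28C and
#' three 8C timepoints, three replicates per species and condition,
#' negative-binomial counts with dispersion 0.05, log-normal baseline
#' means centered on 200, 10% of pairs carrying a planted
#' difference-of-differences effect of |log2| 2.5 at every non-control
#' condition, 1 kb promoters of AT-rich (0.3/0.2/0.2/0.3) background,
#' and 200 annotation terms with sizes log-uniform on 10-300.
#'
#' @param n_pairs number of ortholog pairs.
#' @param conditions condition labels; the first is the control.
#' @param replicates replicates per species x condition.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-pair baseline mean.
#' @param phi NB dispersion (0 = Poisson).
#' @param fraction_divergent fraction of pairs with a planted effect.
#' @param effect_log2 absolute planted difference-of-differences effect
#'   (log2), applied to species B at every non-control condition with a
#'   random sign per pair.
#' @param species_sd,condition_sd log2 SDs of the (non-divergent)
#'   species and shared condition effects.
#' @param lib_range library-size factors are drawn uniformly from this
#'   range.
#' @param promoter_length promoter length in bases.
#' @param background promoter base composition (A, C, G, T).
#' @param plant_divergent,plant_nondivergent motif planting probability
#'   per pair for divergent / non-divergent pairs.
#' @param n_go_terms number of annotation terms.
#' @param go_size_range term sizes, drawn log-uniformly.
#' @param n_planted_terms number of terms planted as enriched.
#' @param planted_odds odds multiplier favoring divergent pairs among a
#'   planted term's members.
#' @param seed global seed (mandatory for reproducibility).
#' @return list of class `xdg_sim_config`.
#' @export
sim_config <- function(n_pairs = 2000,
                       conditions = c("28C", "8C_0h", "8C_6h", "8C_12h"),
                       replicates = 3,
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       phi = 0.05,
                       fraction_divergent = 0.1, effect_log2 = 2.5,
                       species_sd = 0.5, condition_sd = 0.5,
                       lib_range = c(0.7, 1.3),
                       promoter_length = 1000,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       plant_divergent = 0.6, plant_nondivergent = 0.1,
                       n_go_terms = 200, go_size_range = c(10, 300),
                       n_planted_terms = 1, planted_odds = 8,
                       seed = 1L) {
  stopifnot(n_pairs >= 1, length(conditions) >= 2, replicates >= 2,
            phi >= 0, fraction_divergent >= 0, fraction_divergent <= 1,
            is.finite(effect_log2),
            plant_divergent >= 0, plant_divergent <= 1,
            plant_nondivergent >= 0, plant_nondivergent <= 1,
            length(seed) == 1, is.finite(seed))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "xdg_sim_config")
}

#' Simulate two-species NB count matrices with planted divergence
#'
#' Counts are drawn `NB(mu, phi)` with
#' `log2 mu = baseline + species effect + condition effect +
#' planted interaction + log2 library factor`; the species and condition
#' effects are shared across conditions / species respectively, so only
#' the planted interaction creates a difference-of-differences signal.
#' The planted effect is added to species B at every non-control
#' condition.
#'
#' @param cfg an [sim_config()] object.
#' @return list: `counts_a`, `counts_b` (tibbles, first column
#'   `gene_id`), `samples` (sample sheet with `sample`, `species`,
#'   `condition`, `replicate`), `map` (ortholog map tibble `gene_a`,
#'   `gene_b`), `truth` (tibble `pair_id`, `gene_a`, `gene_b`,
#'   `is_divergent`, `true_log2fc`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "xdg_sim_config"))
  set.seed(cfg$seed + 1L)
  np <- cfg$n_pairs
  conds <- cfg$conditions
  reps <- cfg$replicates
  gene_a <- sprintf("A%04d", seq_len(np))
  gene_b <- sprintf("B%04d", seq_len(np))
  pair_id <- paste(gene_a, gene_b, sep = "|")
  n_div <- round(cfg$fraction_divergent * np)
  is_div <- seq_len(np) <= n_div  # ids are arbitrary; no need to shuffle
  sign_ <- sample(c(-1, 1), np, replace = TRUE)
  true_fc <- ifelse(is_div, sign_ * cfg$effect_log2, 0)
  baseline <- stats::rlnorm(np, cfg$baseline_meanlog, cfg$baseline_sdlog)
  sp_eff <- stats::rnorm(np, 0, cfg$species_sd)            # log2, species B
  cond_eff <- matrix(stats::rnorm(np * (length(conds) - 1), 0, cfg$condition_sd),
                     np, length(conds) - 1)                 # log2, shared
  cond_eff <- cbind(0, cond_eff)
  colnames(cond_eff) <- conds
  samples <- tidyr::expand_grid(species = c("A", "B"), condition = conds,
                                replicate = seq_len(reps))
  samples <- dplyr::mutate(samples,
                           sample = paste(.data$species, .data$condition,
                                          .data$replicate, sep = "_"),
                           .before = 1)
  lib_fac <- stats::runif(nrow(samples), cfg$lib_range[1], cfg$lib_range[2])
  draw <- function(mu) {
    if (cfg$phi < 1e-10) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / cfg$phi, mu = mu)
  }
  counts <- matrix(0L, np, nrow(samples),
                   dimnames = list(pair_id, samples$sample))
  for (k in seq_len(nrow(samples))) {
    sp <- samples$species[k]; cd <- samples$condition[k]
    l2 <- log2(baseline) + cond_eff[, cd]
    if (sp == "B") {
      l2 <- l2 + sp_eff
      if (cd != conds[1]) l2 <- l2 + true_fc
    }
    counts[, k] <- draw(2^l2 * lib_fac[k])
  }
  a_cols <- samples$sample[samples$species == "A"]
  b_cols <- samples$sample[samples$species == "B"]
  ca <- counts[, a_cols, drop = FALSE]; rownames(ca) <- gene_a
  cb <- counts[, b_cols, drop = FALSE]; rownames(cb) <- gene_b
  list(counts_a = counts_to_tibble(ca),
       counts_b = counts_to_tibble(cb),
       samples = samples,
       map = tibble::tibble(gene_a = gene_a, gene_b = gene_b),
       truth = tibble::tibble(pair_id = pair_id, gene_a = gene_a,
                              gene_b = gene_b, is_divergent = is_div,
                              true_log2fc = true_fc))
}

# sample one motif instance from the PFM column base frequencies
#' @noRd
sample_motif_instance <- function(pfm) {
  prob <- sweep(pfm, 2, colSums(pfm), "/")
  paste(vapply(seq_len(ncol(pfm)), function(j)
    sample(DNA_BASES, 1, prob = prob[, j]), character(1)), collapse = "")
}

#' Simulate promoter sets with planted motif occurrences
#'
#' Generates i.i.d. background promoters for both species of every pair
#' and plants one motif instance -- sampled from the PFM column
#' frequencies -- at a random offset, independently in each species'
#' promoter with the per-group probability (`plant_divergent` for
#' divergent pairs, `plant_nondivergent` otherwise). Placements are
#' recorded.
#'
#' @param cfg an [sim_config()] object.
#' @param truth truth table from [simulate_counts()].
#' @param pfm 4 x L count matrix of the planted motif.
#' @param motif_id identifier recorded for placements.
#' @return list: `promoters_a`, `promoters_b` (tibbles `gene_id`,
#'   `sequence`), `placements` (tibble `pair_id`, `species`, `motif_id`,
#'   `offset`, `instance`).
#' @export
simulate_promoters <- function(cfg, truth, pfm, motif_id = "planted") {
  stopifnot(inherits(cfg, "xdg_sim_config"),
            all(c("pair_id", "gene_a", "gene_b", "is_divergent") %in% names(truth)))
  pfm <- as.matrix(pfm)
  W <- cfg$promoter_length
  L <- ncol(pfm)
  if (L > W) stop("motif is longer than the promoter")
  set.seed(cfg$seed + 2L)
  bg <- cfg$background / sum(cfg$background)
  np <- nrow(truth)
  rand_seq <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE, prob = bg), collapse = "")
  }
  seqs_a <- vapply(seq_len(np), function(i) rand_seq(W), character(1))
  seqs_b <- vapply(seq_len(np), function(i) rand_seq(W), character(1))
  p_plant <- ifelse(truth$is_divergent, cfg$plant_divergent, cfg$plant_nondivergent)
  placements <- list()
  for (sp in c("A", "B")) {
    planted <- stats::runif(np) < p_plant
    for (i in which(planted)) {
      off <- sample.int(W - L + 1L, 1) - 1L  # 0-based
      inst <- sample_motif_instance(pfm)
      if (sp == "A") {
        substr(seqs_a[i], off + 1, off + L) <- inst
      } else {
        substr(seqs_b[i], off + 1, off + L) <- inst
      }
      placements[[length(placements) + 1L]] <-
        tibble::tibble(pair_id = truth$pair_id[i], species = sp,
                       motif_id = motif_id, offset = off, instance = inst)
    }
  }
  list(promoters_a = tibble::tibble(gene_id = truth$gene_a, sequence = seqs_a),
       promoters_b = tibble::tibble(gene_id = truth$gene_b, sequence = seqs_b),
       placements = if (length(placements)) dplyr::bind_rows(placements)
       else tibble::tibble(pair_id = character(), species = character(),
                           motif_id = character(), offset = integer(),
                           instance = character()))
}

#' Simulate a gene-set annotation with planted enriched terms
#'
#' Unplanted terms draw members uniformly from all pairs; planted terms
#' draw members with sampling weight `planted_odds` for divergent pairs,
#' creating genuine over-representation. Unplanted term sizes are
#' log-uniform on `go_size_range`; planted terms get the fixed geometric
#' midpoint of that range, so the strength of the planted signal does
#' not depend on a size draw.
#'
#' @param cfg an [sim_config()] object.
#' @param truth truth table from [simulate_counts()].
#' @return list: `annotation` (tibble `term_id`, `term_name`,
#'   `gene_id`, keyed by pair id), `planted_terms` (character).
#' @export
simulate_go <- function(cfg, truth) {
  stopifnot(inherits(cfg, "xdg_sim_config"))
  set.seed(cfg$seed + 3L)
  np <- nrow(truth)
  nt <- cfg$n_go_terms
  if (nt == 0L) {
    return(list(annotation = tibble::tibble(term_id = character(),
                                            term_name = character(),
                                            gene_id = character()),
                planted_terms = character()))
  }
  sizes <- pmin(np, round(exp(stats::runif(
    nt, log(cfg$go_size_range[1]), log(cfg$go_size_range[2])))))
  planted <- seq_len(min(cfg$n_planted_terms, nt))
  sizes[planted] <- min(np, round(sqrt(prod(cfg$go_size_range))))
  w_planted <- ifelse(truth$is_divergent, cfg$planted_odds, 1)
  ann <- purrr::map_dfr(seq_len(nt), function(t) {
    w <- if (t %in% planted) w_planted else rep(1, np)
    members <- sample(truth$pair_id, sizes[t], prob = w)
    tibble::tibble(term_id = sprintf("T%04d", t),
                   term_name = sprintf("synthetic process %04d", t),
                   gene_id = members)
  })
  list(annotation = ann, planted_terms = sprintf("T%04d", planted))
}
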