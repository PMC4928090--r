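sim_small <- function(n_pairs = 120, fraction = 0.15, effect = 2.5, seed = 4,
                      sdlog = 0.3) {
  cfg <- sim_config(n_pairs = n_pairs, baseline_sdlog = sdlog,
                    fraction_divergent = fraction, effect_log2 = effect,
                    seed = seed)
  simulate_counts(cfg)
}

test_that("ortholog merging keeps expressed pairs and joins the samples", {
  ca <- counts_tbl(matrix(c(5, 8, 2, 9, 7, 3), 3, 2,
                          dimnames = list(c("a1", "a2", "a3"), c("sA1", "sA2"))))
  cb <- counts_tbl(matrix(c(4, 6, 1, 5, 9, 2), 3, 2,
                          dimnames = list(c("b1", "b2", "b3"), c("sB1", "sB2"))))
  map <- tibble::tibble(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"))
  joint <- merge_ortholog_counts(ca, cb, map, min_count = 1, min_samples = 2)
  expect_equal(nrow(joint), 3)
  expect_equal(names(joint), c("pair_id", "gene_a", "gene_b",
                               "sA1", "sA2", "sB1", "sB2"))
  # pair with a missing species-B gene is dropped and reported
  map2 <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b9"))
  expect_message(j2 <- merge_ortholog_counts(ca, cb, map2, min_samples = 2),
                 "dropped")
  expect_equal(j2$pair_id, "a1|b1")
  expect_equal(attr(j2, "dropped")$reason, "missing")
})

test_that("the expression filter drops exactly the unexpressed pairs", {
  set.seed(9)
  n <- 500
  ma <- matrix(rpois(n * 6, 30), n, 6,
               dimnames = list(sprintf("a%03d", 1:n), paste0("sA", 1:6)))
  mb <- matrix(rpois(n * 6, 30), n, 6,
               dimnames = list(sprintf("b%03d", 1:n), paste0("sB", 1:6)))
  # make 50 species-B genes fail the "count >= 1 in >= 3 samples" filter
  mb[1:50, ] <- 0L
  mb[1:50, 1:2] <- 5L
  map <- tibble::tibble(gene_a = rownames(ma), gene_b = rownames(mb))
  expect_message(joint <- merge_ortholog_counts(counts_tbl(ma), counts_tbl(mb),
                                                map, 1, 3))
  expect_equal(nrow(joint), 450)
})

test_that("a duplicated map id raises an error naming it", {
  ca <- counts_tbl(matrix(1:4, 2, 2, dimnames = list(c("a1", "a2"), c("s1", "s2"))))
  cb <- counts_tbl(matrix(1:4, 2, 2, dimnames = list(c("b1", "b2"), c("t1", "t2"))))
  map <- tibble::tibble(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"))
  expect_error(merge_ortholog_counts(ca, cb, map), "a1")
})

test_that("the interaction contrast has the stated structure", {
  lv <- c("A:28C", "A:8C_0h", "A:8C_12h", "B:28C", "B:8C_0h", "B:8C_12h")
  v <- divergence_contrast(lv, "8C_0h", "28C")
  expect_equal(v[["B:8C_0h"]], 1)
  expect_equal(v[["B:28C"]], -1)
  expect_equal(v[["A:8C_0h"]], -1)
  expect_equal(v[["A:28C"]], 1)
  expect_equal(sum(v), 0)
  expect_equal(sum(v != 0), 4)
  expect_error(divergence_contrast(lv, "8C_6h", "28C"), "8C_6h")
})

test_that("identical responses in both species give a null contrast value", {
  beta <- c("A:28C" = 2, "A:8C_0h" = 3.2, "B:28C" = 4, "B:8C_0h" = 5.2)
  v <- divergence_contrast(names(beta), "8C_0h", "28C")
  expect_equal(sum(v * beta), 0)
})

test_that("planted interactions are recovered and the sign convention holds", {
  b <- sim_small(n_pairs = 150, fraction = 0.2, effect = 2.0, seed = 14,
                 sdlog = 0)
  joint <- merge_ortholog_counts(b$counts_a, b$counts_b, b$map)
  div <- call_divergent(joint, b$samples, timepoints = "8C_0h")
  truth <- b$truth
  est <- div$log2fc[match(truth$pair_id, div$pair_id)]
  planted <- truth$is_divergent
  # mean estimate of the planted effect within +-0.3 of the truth
  expect_lt(abs(mean(est[planted] * sign(truth$true_log2fc[planted])) - 2.0), 0.3)
  # swapping species labels flips the contrast sign
  samples_swapped <- dplyr::mutate(b$samples,
                                   species = ifelse(.data$species == "A", "B", "A"))
  div_sw <- call_divergent(joint, samples_swapped, timepoints = "8C_0h")
  expect_equal(div_sw$log2fc, -div$log2fc, tolerance = 1e-6)
})

test_that("the contrast equals the log ratio-of-ratios of fitted cell means", {
  b <- sim_small(n_pairs = 10, fraction = 0.5, seed = 6)
  joint <- merge_ortholog_counts(b$counts_a, b$counts_b, b$map)
  m <- as.matrix(joint[, -(1:3)])
  samples <- b$samples[match(colnames(m), b$samples$sample), ]
  lv <- paste(samples$species, samples$condition, sep = ":")
  X <- model.matrix(~ 0 + factor(lv, levels = unique(lv)))
  colnames(X) <- unique(lv)
  offs <- log(colSums(m))
  cvec <- divergence_contrast(colnames(X), "8C_0h", "28C")
  for (i in 1:5) {
    f <- fit_nb_glm(m[i, ], X, offs, dispersion = 0.05)
    # normalized fitted mean per cell: mu_s / exp(offset_s), constant in a cell
    cell_mean <- vapply(colnames(X), function(lev) {
      s <- which(lv == lev)[1]
      f$mu[s] / exp(offs[s])
    }, numeric(1))
    rr <- log2((cell_mean["B:8C_0h"] / cell_mean["B:28C"]) /
                 (cell_mean["A:8C_0h"] / cell_mean["A:28C"]))
    expect_equal(sum(cvec * f$beta) / log(2), unname(rr), tolerance = 1e-6)
  }
})

test_that("the divergent union equals the OR of per-timepoint flags", {
  b <- sim_small(n_pairs = 80, seed = 19)
  joint <- merge_ortholog_counts(b$counts_a, b$counts_b, b$map)
  div <- call_divergent(joint, b$samples, timepoints = c("8C_0h", "8C_12h"))
  by_or <- unique(div$pair_id[div$is_divergent])
  expect_setequal(divergent_union(div), by_or)
  gl <- glance(div)
  expect_equal(unique(gl$n_union), length(by_or))
  expect_error(call_divergent(joint, b$samples, timepoints = "8C_99h"), "8C_99h")
})
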