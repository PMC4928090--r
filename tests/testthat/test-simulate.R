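test_that("generators are byte-deterministic given the seed", {
  cfg <- sim_config(n_pairs = 40, seed = 99)
  b1 <- simulate_counts(cfg)
  b2 <- simulate_counts(cfg)
  expect_identical(b1, b2)
  p1 <- simulate_promoters(cfg, b1$truth, strong_pfm())
  p2 <- simulate_promoters(cfg, b1$truth, strong_pfm())
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_promoters(p1$promoters_a, f1)
  write_promoters(p2$promoters_a, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- simulate_go(cfg, b1$truth)
  g2 <- simulate_go(cfg, b1$truth)
  expect_identical(g1, g2)
})

test_that("per-component seeds are independent of call order", {
  cfg <- sim_config(n_pairs = 30, seed = 7)
  b1 <- simulate_counts(cfg)
  invisible(simulate_go(cfg, b1$truth))      # interleave another generator
  invisible(simulate_promoters(cfg, b1$truth, strong_pfm()))
  b2 <- simulate_counts(cfg)
  expect_identical(b1$counts_a, b2$counts_a)
})

test_that("simulated counts follow the NB mean-variance relationship", {
  cfg <- sim_config(n_pairs = 2000, replicates = 10, phi = 0.2,
                    baseline_sdlog = 1, fraction_divergent = 0,
                    lib_range = c(1, 1), conditions = c("28C", "8C_0h"),
                    seed = 5)
  b <- simulate_counts(cfg)
  m <- as.matrix(b$counts_a[, -1])
  cols <- grepl("_28C_", colnames(m))
  mu_hat <- rowMeans(m[, cols])
  v_hat <- apply(m[, cols], 1, var)
  keep <- mu_hat > 50
  ratio <- v_hat[keep] / (mu_hat[keep] + 0.2 * mu_hat[keep]^2)
  expect_equal(median(ratio), 1, tolerance = 0.15)
  # and clearly overdispersed relative to Poisson
  expect_gt(median(v_hat[keep] / mu_hat[keep]), 2)
})

test_that("planted truth matches the emitted design", {
  cfg <- sim_config(n_pairs = 50, fraction_divergent = 0.2, seed = 3)
  b <- simulate_counts(cfg)
  expect_equal(sum(b$truth$is_divergent), 10)
  expect_true(all(abs(b$truth$true_log2fc[b$truth$is_divergent]) == 2.5))
  expect_true(all(b$truth$true_log2fc[!b$truth$is_divergent] == 0))
  expect_equal(nrow(b$samples), 2 * 4 * 3)
  expect_setequal(names(b$counts_a)[-1],
                  b$samples$sample[b$samples$species == "A"])
})

test_that("promoter planting respects group probabilities and placements", {
  cfg <- sim_config(n_pairs = 400, fraction_divergent = 0.5,
                    plant_divergent = 1, plant_nondivergent = 0, seed = 11)
  b <- simulate_counts(cfg)
  prom <- simulate_promoters(cfg, b$truth, strong_pfm(), motif_id = "MX")
  planted_pairs <- unique(prom$placements$pair_id)
  expect_true(all(planted_pairs %in% b$truth$pair_id[b$truth$is_divergent]))
  # probability-1 planting in both species: two placements per divergent pair
  expect_equal(nrow(prom$placements), 2 * sum(b$truth$is_divergent))
  # each recorded placement is really in the sequence
  for (i in sample(nrow(prom$placements), 20)) {
    pl <- prom$placements[i, ]
    seqs <- if (pl$species == "A") prom$promoters_a else prom$promoters_b
    idx <- match(pl$pair_id, b$truth$pair_id)
    expect_equal(substr(seqs$sequence[idx], pl$offset + 1, pl$offset + 10),
                 pl$instance)
  }
  expect_error(simulate_promoters(sim_config(promoter_length = 5, seed = 1),
                                  b$truth, strong_pfm()), "longer")
})

test_that("annotation planting and the empty-term edge case behave", {
  cfg <- sim_config(n_pairs = 300, n_go_terms = 50, seed = 13)
  b <- simulate_counts(cfg)
  g <- simulate_go(cfg, b$truth)
  expect_equal(g$planted_terms, "T0001")
  expect_equal(dplyr::n_distinct(g$annotation$term_id), 50)
  sizes <- table(g$annotation$term_id)
  expect_true(all(sizes >= 10 & sizes <= 300))
  g0 <- simulate_go(sim_config(n_go_terms = 0, seed = 1), b$truth)
  expect_equal(nrow(g0$annotation), 0)
  expect_named(g0$annotation, c("term_id", "term_name", "gene_id"))
})
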