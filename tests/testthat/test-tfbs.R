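test_that("Fisher exact test reproduces hand-enumerable tables", {
  ft <- fisher_exact(15, 9, 8, 33)
  expect_equal(ft$pvalue, 9.84e-4, tolerance = 1e-3)
  expect_equal(round(ft$odds_ratio, 2), 6.63)
  # symmetric table: no association
  ft2 <- fisher_exact(5, 5, 5, 5)
  expect_equal(ft2$pvalue, 1)
  expect_equal(ft2$odds_ratio, 1, tolerance = 1e-6)
  # perfect separation on a support of 4 tables: two tables of prob 1/20
  ft3 <- fisher_exact(3, 0, 0, 3)
  expect_equal(ft3$pvalue, 0.1, tolerance = 1e-12)
  expect_equal(ft3$odds_ratio, Inf)
  # zero margin: P = 1, odds ratio undefined
  ft4 <- fisher_exact(0, 0, 5, 7)
  expect_equal(ft4$pvalue, 1)
  expect_true(is.nan(ft4$odds_ratio))
  expect_false(ft4$or_defined)
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher P and CMLE odds ratio match the reference implementation", {
  set.seed(41)
  for (k in 1:100) {
    tab <- rmultinom(1, sample(8:60, 1), prob = runif(4, 0.05, 1))[, 1]
    ft <- fisher_exact(tab[1], tab[2], tab[3], tab[4])
    ref <- fisher.test(matrix(tab, 2, byrow = TRUE))
    expect_equal(ft$pvalue, ref$p.value, tolerance = 1e-9)
    if (is.finite(ft$odds_ratio) && ft$odds_ratio > 1e-3 &&
        ft$odds_ratio < 1e3 && is.finite(ref$estimate)) {
      # fisher.test maximizes the same conditional likelihood numerically;
      # agreement is limited by its optimizer tolerance, which degrades
      # where the conditional score equation is nearly flat (extreme ORs)
      expect_equal(ft$odds_ratio, unname(ref$estimate),
                   tolerance = if (ft$odds_ratio > 50) 5e-3 else 2e-3)
    }
    expect_equal(ft$pvalue, fisher_p_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("the conditional MLE shrinks below the cross-product odds ratio", {
  set.seed(43)
  checked <- 0
  while (checked < 40) {
    tab <- rmultinom(1, sample(20:60, 1), prob = c(0.35, 0.15, 0.15, 0.35))[, 1]
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if (any(c(a, b, c, d) == 0) || a * d <= b * c) next
    ft <- fisher_exact(a, b, c, d)
    expect_gt(ft$odds_ratio, 0)
    expect_lt(ft$odds_ratio, (a * d) / (b * c) + 1e-9)
    checked <- checked + 1
  }
})

test_that("the presence rule is an either-species OR and symmetric", {
  map <- tibble::tibble(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4))
  hits_a <- tibble::tibble(gene_id = "a1", motif_id = "M1")
  hits_b <- tibble::tibble(gene_id = c("b2", "b4"), motif_id = "M1")
  pres <- build_presence(hits_a, hits_b, map, motif_ids = "M1")
  expect_equal(pres$M1, c(TRUE, TRUE, FALSE, TRUE))
  # swapping species leaves presence unchanged
  map_sw <- tibble::tibble(gene_a = map$gene_b, gene_b = map$gene_a)
  pres_sw <- build_presence(hits_b, hits_a, map_sw, motif_ids = "M1")
  expect_equal(pres_sw$M1, pres$M1)
  # pairs missing a promoter are excluded
  proms_a <- tibble::tibble(gene_id = paste0("a", 1:3))
  expect_message(pres2 <- build_presence(hits_a, hits_b, map,
                                         promoters_a = proms_a,
                                         motif_ids = "M1"), "excluded")
  expect_equal(nrow(pres2), 3)
})

test_that("a planted presence fixture reproduces the Fisher row", {
  # 65 pairs: 24 divergent of which 15 contain the motif; 41 others, 8 contain
  pair_id <- sprintf("p%02d", 1:65)
  divergent <- pair_id[1:24]
  pres <- tibble::tibble(pair_id = pair_id,
                         M1 = c(rep(TRUE, 15), rep(FALSE, 9),
                                rep(TRUE, 8), rep(FALSE, 33)))
  res <- enrich_tfbs(pres, divergent)
  expect_equal(res$present_divergent, 15)
  expect_equal(res$absent_nondivergent, 33)
  ft <- fisher_exact(15, 9, 8, 33)
  expect_equal(res$pvalue, ft$pvalue)
  expect_equal(res$odds_ratio, ft$odds_ratio)
  expect_true(res$enriched)
  # a motif present everywhere is uninformative
  pres$M2 <- TRUE
  res2 <- enrich_tfbs(pres, divergent)
  expect_equal(res2$pvalue[res2$motif_id == "M2"], 1)
  expect_error(enrich_tfbs(pres, divergent, scope = character(0)), "empty scope")
  expect_error(enrich_tfbs(pres, divergent, scope = "nope"), "nope")
})

test_that("permuted divergence labels give calibrated motif P-values", {
  set.seed(61)
  n <- 120
  pres <- tibble::tibble(pair_id = sprintf("p%03d", 1:n))
  for (m in 1:8) pres[[paste0("M", m)]] <- runif(n) < runif(1, 0.2, 0.6)
  frac <- vapply(1:50, function(r) {
    divergent <- sample(pres$pair_id, 30)
    mean(enrich_tfbs(pres, divergent)$pvalue < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.08)
})

test_that("apoptosis-related TFs are flagged by the literal keyword rule", {
  ann <- tibble::tibble(
    gene_id = c("tf1", "tf2", "tf3", "tf4", "tf5", "g9"),
    term_name = c("regulation of apoptotic process",
                  "intrinsic apoptosis signaling",
                  "programmed cell death",
                  "Apoptosis-associated signaling",
                  "cell cycle",
                  "apoptotic process"))
  cat <- define_apoptosis_tfs(ann, tf_ids = paste0("tf", 1:10))
  flagged <- cat$gene_id[cat$is_apoptosis_related]
  expect_setequal(flagged, c("tf1", "tf2", "tf4"))
  # a non-TF never counts as an apoptosis-related TF
  expect_false(cat$is_apoptosis_related[cat$gene_id == "g9"])
  expect_true(all(cat$is_tf[cat$is_apoptosis_related]))
})

test_that("fixture with known term counts flags exactly the matching TFs", {
  set.seed(3)
  terms <- c(rep("regulation of apoptotic process", 4),
             rep("transcription", 6))
  ann <- tibble::tibble(gene_id = paste0("tf", 1:10), term_name = terms)
  cat <- define_apoptosis_tfs(ann, paste0("tf", 1:10))
  expect_equal(sum(cat$is_apoptosis_related), 4)
})

test_that("subnetwork connectivity counts query nodes in the largest component", {
  star <- tibble::tibble(source = "hub", target = paste0("tf", 1:4),
                         type = "physical")
  net <- extract_subnetwork(star, nodes = c("hub", paste0("tf", 1:4)))
  expect_equal(net$connectivity, 1)
  # two disjoint pairs plus an isolate
  pairs <- tibble::tibble(source = c("a", "c"), target = c("b", "d"),
                          type = "genetic")
  net2 <- extract_subnetwork(pairs, nodes = c("a", "b", "c", "d", "e"))
  expect_equal(net2$connectivity, 2 / 5)
  expect_true("e" %in% net2$membership$node)
  # intermediates bridge query nodes without counting as queries
  edges <- tibble::tibble(source = c("t1", "t2", "t3", "t4"),
                          target = c("mid", "mid", "mid", "t3"),
                          type = "physical")
  net3 <- extract_subnetwork(edges, nodes = c("t1", "t2", "t3", "t4"),
                             intermediates = "mid")
  expect_equal(net3$connectivity, 1)
  net4 <- extract_subnetwork(edges, nodes = c("t1", "t2", "t3", "t4"))
  expect_equal(net4$connectivity, 2 / 4)
  gl <- glance(net3)
  expect_equal(gl$n_query, 4)
})
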