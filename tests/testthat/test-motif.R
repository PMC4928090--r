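test_that("JASPAR parsing handles both row styles and validates counts", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">M0001 factor_one",
    "A [ 10  2  0 ]",
    "C [  0  8  1 ]",
    "G [  0  0  9 ]",
    "T [  0  0  0 ]",
    ">M0002 factor_two",
    "1 2",
    "3 4",
    "5 6",
    "7 8"), path)
  motifs <- read_jaspar(path)
  expect_equal(motifs$motif_id, c("M0001", "M0002"))
  expect_equal(motifs$name, c("factor_one", "factor_two"))
  expect_equal(motifs$pfm[[1]]["A", ], c(10, 2, 0))
  expect_equal(motifs$pfm[[2]]["T", ], c(7, 8))
  writeLines(c(">bad m", "0 0", "0 0", "0 0", "0 0"), path)
  expect_error(read_jaspar(path), "all-zero")
})

test_that("PFM to PWM conversion matches the hand-computed log-odds", {
  # single-base column without pseudocount: log2(4) vs the floor
  pwm0 <- pfm_to_pwm(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(pwm0$mat["A", 1]), log2(4))
  expect_equal(unname(pwm0$mat[c("C", "G", "T"), 1]), rep(-30, 3))
  # uniform counts, uniform background: no information, all zero
  pwm1 <- pfm_to_pwm(matrix(5, 4, 2))
  expect_true(all(pwm1$mat == 0))
  # hand computation with pseudocount 0.1 spread by background
  pfm <- matrix(c(12, 3, 4, 1,  0, 15, 2, 3), 4, 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  bg <- c(0.3, 0.2, 0.2, 0.3)
  pwm <- pfm_to_pwm(pfm, background = bg, pseudocount = 0.1)
  hand <- log2(((pfm + 0.1 * bg) / rep(colSums(pfm) + 0.1, each = 4)) / bg)
  expect_equal(unname(pwm$mat), unname(hand), tolerance = 1e-9)
  expect_error(pfm_to_pwm(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2)), "all-zero")
})

test_that("the DP score distribution is exact", {
  # single column, uniform background: each score carries mass 1/4
  pwm1 <- pfm_to_pwm(matrix(c(10, 5, 3, 2), 4, 1))
  nt1 <- score_pvalue_table(pwm1)
  expect_equal(pwm_tail_prob(nt1, max(nt1$int_mat)), 0.25)
  expect_equal(pwm_tail_prob(nt1, nt1$min_int), 1)
  expect_equal(pwm_tail_prob(nt1, nt1$min_int - 100L), 1)
  # enumeration oracle for motif lengths 2..6, uniform and skewed
  for (L in 2:6) {
    for (bg in list(rep(0.25, 4), c(0.4, 0.1, 0.15, 0.35))) {
      pwm <- pfm_to_pwm(random_pfm(L, seed = 100 + L), background = bg)
      nt <- score_pvalue_table(pwm)
      ks <- nt$min_int + seq(0, length(nt$tail) - 1)
      probe <- ks[round(seq(1, length(ks), length.out = 25))]
      expect_equal(pwm_tail_prob(nt, probe),
                   pwm_tail_bruteforce(nt, bg, probe), tolerance = 1e-9)
    }
  }
})

test_that("planted sites are found on both strands at the right offsets", {
  pfm <- strong_pfm()
  pwm <- pfm_to_pwm(pfm, motif_id = "M1")
  cons <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  s <- random_dna(1000, seed = 55)
  substr(s, 101, 110) <- cons  # 0-based offset 100
  hits <- scan_promoter(s, pwm)
  expect_true(any(hits$strand == "+" & hits$offset == 100))
  # planting the reverse complement is reported on the minus strand
  rc_cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  s2 <- random_dna(1000, seed = 56)
  substr(s2, 301, 310) <- rc_cons
  hits2 <- scan_promoter(s2, pwm)
  expect_true(any(hits2$strand == "-" & hits2$offset == 300))
  expect_equal(nrow(scan_promoter(strrep("N", 500), pwm)), 0)
  expect_equal(nrow(scan_promoter("ACGT", pwm)), 0)  # shorter than the motif
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  pwm <- pfm_to_pwm(random_pfm(6, seed = 77), motif_id = "M2")
  s <- random_dna(600, seed = 78)
  h_fwd <- scan_promoter(s, pwm, threshold = 0.01)
  h_rc <- scan_promoter(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), pwm, threshold = 0.01)
  # mirrored coordinates, flipped strand
  key <- function(h, W, L) {
    sort(paste(ifelse(h$strand == "+", "-", "+"), W - L - h$offset, round(h$score, 6)))
  }
  expect_equal(sort(paste(h_fwd$strand, h_fwd$offset, round(h_fwd$score, 6))),
               key(h_rc, 600, 6))
  h_tight <- scan_promoter(s, pwm, threshold = 1e-4)
  expect_true(all(paste(h_tight$strand, h_tight$offset) %in%
                    paste(h_fwd$strand, h_fwd$offset)))
})

test_that("null hit counts match the exact per-window probability", {
  pwm <- pfm_to_pwm(strong_pfm(), motif_id = "M1")
  nt <- score_pvalue_table(pwm)
  th <- 1e-3
  # exact per-window hit probability at the discretized cutoff
  ks <- nt$min_int + seq(0, length(nt$tail) - 1)
  p_cut <- max(nt$tail[nt$tail < th], 0)
  set.seed(91)
  proms <- tibble::tibble(
    gene_id = sprintf("p%03d", 1:200),
    sequence = vapply(1:200, function(i) random_dna(500), character(1)))
  hits <- scan_promoters(proms, list(pwm), threshold = th, background = "uniform")
  n_windows <- 200 * 2 * (500 - 10 + 1)
  expected <- n_windows * p_cut
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 3)
})

test_that("batch scanning equals per-promoter scanning", {
  pwm <- pfm_to_pwm(random_pfm(5, seed = 31), motif_id = "M3")
  set.seed(32)
  proms <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    sequence = vapply(1:20, function(i)
      random_dna(sample(50:200, 1), prob = c(.3, .2, .2, .3)), character(1)))
  batch <- scan_promoters(proms, list(pwm), threshold = 0.01,
                          background = "uniform")
  single <- purrr::map_dfr(1:20, function(i) {
    h <- scan_promoter(proms$sequence[i], pwm, 0.01)
    if (nrow(h)) dplyr::bind_cols(tibble::tibble(gene_id = proms$gene_id[i]), h)
  })
  single <- dplyr::arrange(single, .data$gene_id, .data$offset, .data$strand)
  expect_equal(as.data.frame(batch), as.data.frame(single))
})
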