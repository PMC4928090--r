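# Shared fixtures and independent oracles. The oracles deliberately use
# different machinery than the implementation (stats::dhyper / phyper /
# fisher.test, brute-force enumeration, grid searches).

# small two-group count fixture: genes x (2 conditions x reps)
make_two_group_counts <- function(n_genes = 100, reps = 3, mu = 50, phi = 0.1,
                                  seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * 2 * reps, size = 1 / max(phi, 1e-8), mu = mu),
              n_genes, 2 * reps,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              c(paste0("ctl_", seq_len(reps)),
                                paste0("trt_", seq_len(reps)))))
  list(counts = counts_tbl(m),
       samples = tibble::tibble(
         sample = colnames(m),
         condition = rep(c("ctl", "trt"), each = reps),
         replicate = rep(seq_len(reps), 2)))
}

counts_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

# Fisher two-sided P oracle: full enumeration over the conditional
# support using stats::dhyper point probabilities.
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(x, r1, r2, c1)
  p0 <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# Fisher two-sided P by exact integer arithmetic: numerators and the
# common denominator are integers represented exactly in doubles
# (all choose() products stay below 2^53 for N <= 28).
fisher_p_exact_rational <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, x) * choose(r2, c1 - x)   # exact integers
  den <- choose(r1 + r2, c1)
  n0 <- num[x == a]
  sum(num[num <= n0]) / den
}

# upper-tail hypergeometric oracle (survival function)
hypergeom_oracle <- function(N, n, M, i) {
  phyper(i - 1, M, N - M, n, lower.tail = FALSE)
}

# brute-force tail of the discretized PWM score distribution: enumerate
# all 4^L k-mers with background weights
pwm_tail_bruteforce <- function(null_table, background, k_values) {
  L <- ncol(null_table$int_mat)
  kmers <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(null_table$int_mat[cbind(as.vector(kmers),
                                                rep(seq_len(L), each = nrow(kmers)))],
                       nrow(kmers), L))
  pr <- apply(kmers, 1, function(kk) prod(background[kk]))
  vapply(k_values, function(k) sum(pr[sc >= k]), numeric(1))
}

random_pfm <- function(L, seed, strength = 30) {
  set.seed(seed)
  m <- matrix(rpois(4 * L, 5) + 1, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) m[sample(4, 1), j] <- m[sample(4, 1), j] + strength
  m
}

# the strong 10-column site used by the planted-motif simulations
strong_pfm <- function() {
  rbind(A = c(90, 2, 2, 90, 2, 2, 90, 2, 2, 90),
        C = c(4, 2, 90, 2, 2, 90, 4, 2, 90, 2),
        G = c(4, 90, 4, 4, 90, 4, 4, 90, 4, 4),
        T = c(2, 6, 4, 4, 6, 4, 2, 96, 4, 4))
}

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

table1_fixture <- function() {
  readr::read_tsv(system.file("extdata", "apoptosis_tfbs_counts.tsv",
                              package = "xdiverge"),
                  show_col_types = FALSE)
}
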