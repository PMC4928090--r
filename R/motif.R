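# PWM scanning in the FIMO idiom: position frequency matrices are turned
# into log2-odds matrices against a 0-order background, scores are
# discretized on a fixed granularity, and the exact distribution of the
# score of a background-random k-mer is computed by dynamic programming,
# giving an exact P-value for every attainable score. A window is a hit
# when P(score >= observed) < threshold (default 1e-4).

DNA_BASES <- c("A", "C", "G", "T")

#' Read motifs from a JASPAR-format PFM file
#'
#' Supports the JASPAR text format: a `>ID name` header followed by four
#' count rows, either bare numbers or `A [ 1 2 3 ]` style.
#'
#' @param path file path.
#' @return tibble with columns `motif_id`, `name` and a list-column `pfm`
#'   of 4 x L count matrices (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    toks <- strsplit(header, "\\s+")[[1]]
    body <- lines[(s + 1):e]
    if (length(body) < 4) stop("motif ", toks[1], ": expected 4 count rows")
    rows <- purrr::map(body[1:4], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", trimws(ln))
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop("motif ", toks[1], ": ragged count rows")
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- DNA_BASES
    if (any(pfm < 0)) stop("motif ", toks[1], ": negative counts")
    if (any(colSums(pfm) == 0)) stop("motif ", toks[1], ": all-zero column")
    list(motif_id = toks[1],
         name = if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1],
         pfm = pfm)
  })
  tibble::tibble(motif_id = purrr::map_chr(recs, "motif_id"),
                 name = purrr::map_chr(recs, "name"),
                 pfm = purrr::map(recs, "pfm"))
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Each column is smoothed with a background-distributed pseudocount and
#' log2-scored against the background:
#' `pwm[x, j] = log2((count[x, j] + pc * b[x]) / (total_j + pc) / b[x])`.
#' Cells with zero smoothed probability (possible only at `pseudocount =
#' 0`) are floored at a finite large-negative score.
#'
#' @param pfm 4 x L nonnegative count matrix (rows A, C, G, T).
#' @param background base frequencies summing to 1 (default uniform).
#' @param pseudocount total pseudocount per column, spread by background
#'   frequency (default 0.1).
#' @param floor score floor in bits for zero-probability cells.
#' @param motif_id,name optional identifiers carried on the model.
#' @return list of class `xdg_pwm`: `mat` (4 x L log2-odds),
#'   `background`, `pseudocount`, `length`, `motif_id`, `name`.
#' @export
pfm_to_pwm <- function(pfm, background = NULL, pseudocount = 0.1,
                       floor = -30, motif_id = NULL, name = NULL) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  if (any(pfm < 0)) stop("PFM counts must be nonnegative")
  tot <- colSums(pfm)
  if (any(tot == 0)) stop("PFM has an all-zero column")
  if (is.null(background)) background <- rep(0.25, 4)
  if (length(background) != 4 || any(background <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  background <- background / sum(background)
  prob <- sweep(pfm + pseudocount * background, 2, tot + pseudocount, "/")
  mat <- log2(sweep(prob, 1, background, "/"))
  mat[!is.finite(mat)] <- floor
  mat <- pmax(mat, floor)
  dimnames(mat) <- list(DNA_BASES, NULL)
  structure(list(mat = mat, background = background,
                 pseudocount = pseudocount, length = ncol(mat),
                 motif_id = motif_id, name = name),
            class = "xdg_pwm")
}

#' Exact null distribution of PWM scores by dynamic programming
#'
#' Discretizes each PWM column to integer multiples of `granularity` and
#' convolves, column by column, the distribution of the discretized score
#' of a k-mer drawn from the 0-order background. The result gives the
#' exact tail probability `P(score >= s)` for every attainable
#' discretized score; the discretization error in score units is at most
#' `L * granularity / 2`.
#'
#' @param pwm an `xdg_pwm` model.
#' @param granularity score discretization step in bits (default 1e-3).
#' @return list of class `xdg_pwm_null`: `granularity`, `int_mat`
#'   (discretized 4 x L score matrix), `min_int`, `tail` (vector of
#'   `P(score >= k)` for `k = min_int, min_int + 1, ...`).
#' @export
score_pvalue_table <- function(pwm, granularity = 1e-3) {
  stopifnot(inherits(pwm, "xdg_pwm"))
  int_mat <- round(pwm$mat / granularity)
  b <- pwm$background
  # distribution over integer score sums, tracked as (offset, prob vector)
  lo <- 0L
  p <- 1
  for (j in seq_len(ncol(int_mat))) {
    s <- int_mat[, j]
    new_lo <- lo + min(s)
    new_hi <- lo + length(p) - 1L + max(s)
    np <- numeric(new_hi - new_lo + 1L)
    for (x in 1:4) {
      sh <- lo + s[x] - new_lo
      idx <- seq_along(p) + sh
      np[idx] <- np[idx] + b[x] * p
    }
    p <- np
    lo <- new_lo
  }
  tail <- rev(cumsum(rev(p)))
  structure(list(granularity = granularity, int_mat = int_mat,
                 min_int = lo, tail = tail),
            class = "xdg_pwm_null")
}

# P(score >= k) for integer scores k (vectorized); 1 below the support,
# 0 above it.
#' @noRd
pwm_tail_prob <- function(null_table, k) {
  idx <- k - null_table$min_int + 1L
  n <- length(null_table$tail)
  out <- numeric(length(k))
  out[idx <= 0] <- 1
  inside <- idx >= 1 & idx <= n
  out[inside] <- null_table$tail[idx[inside]]
  out
}

# Integer window scores for an encoded sequence (values 1..4, NA for N).
# Returns a vector over window start offsets (0-based); windows touching
# an N are NA.
#' @noRd
window_scores_int <- function(enc, int_mat) {
  L <- ncol(int_mat)
  W <- length(enc)
  nwin <- W - L + 1L
  if (nwin < 1L) return(numeric(0))
  s <- numeric(nwin)
  for (j in seq_len(L)) {
    s <- s + int_mat[, j][enc[j:(j + nwin - 1L)]]
  }
  s
}

#' @noRd
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
}

#' @noRd
revcomp_chr <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Scan one promoter sequence with a PWM on both strands
#'
#' Scores every window of the sequence and of its reverse complement
#' against the PWM's discretized scores, and reports the windows whose
#' exact null P-value is below `threshold`. Windows containing `N` are
#' skipped. Offsets are 0-based window starts on the input (forward)
#' sequence for both strands.
#'
#' @param sequence promoter sequence (character, A/C/G/T/N).
#' @param pwm an `xdg_pwm` model.
#' @param threshold P-value threshold for reporting a hit (default 1e-4).
#' @param null_table optional precomputed [score_pvalue_table()] result.
#' @return tibble: `motif_id`, `strand` (+/-), `offset`, `score` (bits,
#'   on the discretized grid), `pvalue`.
#' @export
scan_promoter <- function(sequence, pwm, threshold = 1e-4, null_table = NULL) {
  stopifnot(inherits(pwm, "xdg_pwm"), threshold > 0, threshold < 1)
  if (is.null(null_table)) null_table <- score_pvalue_table(pwm)
  L <- pwm$length
  W <- nchar(sequence)
  empty <- tibble::tibble(motif_id = character(), strand = character(),
                          offset = integer(), score = numeric(),
                          pvalue = numeric())
  if (W < L) return(empty)
  g <- null_table$granularity
  one_strand <- function(enc) {
    k <- window_scores_int(enc, null_table$int_mat)
    ok <- which(!is.na(k))
    if (!length(ok)) return(NULL)
    pv <- pwm_tail_prob(null_table, k[ok])
    hit <- pv < threshold
    list(offset = ok[hit] - 1L, k = k[ok][hit], pvalue = pv[hit])
  }
  enc <- encode_dna(sequence)
  fwd <- one_strand(enc)
  rev_ <- one_strand(rev(5L - enc))  # A<->T, C<->G on the integer code
  rows <- list()
  if (!is.null(fwd) && length(fwd$offset)) {
    rows <- c(rows, list(tibble::tibble(
      motif_id = pwm$motif_id %||% NA_character_, strand = "+",
      offset = as.integer(fwd$offset), score = fwd$k * g, pvalue = fwd$pvalue)))
  }
  if (!is.null(rev_) && length(rev_$offset)) {
    rows <- c(rows, list(tibble::tibble(
      motif_id = pwm$motif_id %||% NA_character_, strand = "-",
      offset = as.integer(W - L - rev_$offset), score = rev_$k * g,
      pvalue = rev_$pvalue)))
  }
  if (!length(rows)) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$offset, .data$strand)
}

#' Estimate a 0-order background from a promoter set
#'
#' @param promoters data frame with a `sequence` column (or a character
#'   vector of sequences). `N` bases are ignored.
#' @return numeric(4) base frequencies (A, C, G, T).
#' @export
promoter_background <- function(promoters) {
  seqs <- if (is.data.frame(promoters)) promoters$sequence else promoters
  enc <- match(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]], DNA_BASES)
  counts <- tabulate(enc, nbins = 4)
  if (sum(counts) == 0) stop("no A/C/G/T bases in the promoter set")
  stats::setNames(counts / sum(counts), DNA_BASES)
}

#' Scan a promoter set with a motif collection
#'
#' Converts each PFM to a PWM against a shared background (by default the
#' 0-order composition of the scanned promoter set itself), builds the
#' exact score null once per motif, and scans every promoter on both
#' strands.
#'
#' @param promoters data frame with columns `gene_id`, `sequence`.
#' @param motifs result of [read_jaspar()] (columns `motif_id`, `name`,
#'   list-column `pfm`), or a list of `xdg_pwm` models.
#' @param threshold hit P-value threshold (default 1e-4).
#' @param background `"promoters"` (estimate from the scanned set),
#'   `"uniform"`, or a numeric(4) frequency vector.
#' @param pseudocount passed to [pfm_to_pwm()].
#' @return tibble of hits: `gene_id`, `motif_id`, `strand`, `offset`,
#'   `score`, `pvalue`.
#' @export
scan_promoters <- function(promoters, motifs, threshold = 1e-4,
                           background = "promoters", pseudocount = 0.1) {
  stopifnot(is.data.frame(promoters),
            all(c("gene_id", "sequence") %in% names(promoters)))
  bg <- if (is.numeric(background)) {
    background
  } else if (identical(background, "uniform")) {
    rep(0.25, 4)
  } else {
    promoter_background(promoters)
  }
  pwms <- if (is.data.frame(motifs)) {
    purrr::pmap(motifs[, c("motif_id", "name", "pfm")], function(motif_id, name, pfm) {
      pfm_to_pwm(pfm, background = bg, pseudocount = pseudocount,
                 motif_id = motif_id, name = name)
    })
  } else {
    motifs
  }
  # all promoters are scanned in one pass over a concatenated encoding,
  # with NA separators so no window straddles two promoters
  encs <- lapply(strsplit(toupper(promoters$sequence), ""), match, DNA_BASES)
  widths <- lengths(encs)
  purrr::map_dfr(pwms, function(pwm) {
    nt <- score_pvalue_table(pwm)
    L <- pwm$length
    sep <- rep(NA_integer_, L)
    glue_scan <- function(enc_list) {
      cat_enc <- unlist(lapply(enc_list, function(e) c(e, sep)), use.names = FALSE)
      starts <- cumsum(c(1L, widths + L))[seq_along(enc_list)]
      k <- window_scores_int(cat_enc, nt$int_mat)
      ok <- which(!is.na(k))
      if (!length(ok)) return(NULL)
      pv <- pwm_tail_prob(nt, k[ok])
      hit <- pv < threshold
      if (!any(hit)) return(NULL)
      w <- ok[hit]
      p <- findInterval(w, starts)
      list(prom = p, offset = w - starts[p], k = k[ok][hit], pvalue = pv[hit])
    }
    fwd <- glue_scan(encs)
    rev_ <- glue_scan(lapply(encs, function(e) rev(5L - e)))
    g <- nt$granularity
    rows <- list()
    if (!is.null(fwd)) {
      rows <- c(rows, list(tibble::tibble(
        gene_id = promoters$gene_id[fwd$prom], motif_id = pwm$motif_id,
        strand = "+", offset = as.integer(fwd$offset),
        score = fwd$k * g, pvalue = fwd$pvalue)))
    }
    if (!is.null(rev_)) {
      rows <- c(rows, list(tibble::tibble(
        gene_id = promoters$gene_id[rev_$prom], motif_id = pwm$motif_id,
        strand = "-", offset = as.integer(widths[rev_$prom] - L - rev_$offset),
        score = rev_$k * g, pvalue = rev_$pvalue)))
    }
    if (!length(rows)) {
      return(tibble::tibble(gene_id = character(), motif_id = character(),
                            strand = character(), offset = integer(),
                            score = numeric(), pvalue = numeric()))
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$gene_id, .data$offset,
                   .data$strand)
  })
}
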