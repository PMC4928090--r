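# TSS and promoter extraction. Coordinates are 0-based half-open
# internally; transcript tables arrive 1-based inclusive (GFF dialect)
# and the TSS is reported 0-based. The promoter is the `length` bases
# immediately upstream of the TSS in gene orientation, excluding the TSS
# base itself, truncated at contig edges.

#' Read transcript records from a GFF3 file
#'
#' Extracts transcript-level features (`mRNA`/`transcript`) with their
#' gene assignment. Transcripts lacking exon children are skipped with a
#' message. When a `canonical` attribute tag is present it is carried
#' through so [extract_tss()] can pick the canonical model.
#'
#' @param path GFF3 file path.
#' @return tibble: `gene_id`, `transcript_id`, `contig`, `strand`,
#'   `start`, `end` (1-based inclusive), `canonical` (logical).
#' @export
read_transcripts_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  is_tx <- md$type %in% c("mRNA", "transcript")
  tx <- md[is_tx, , drop = FALSE]
  if (!nrow(tx)) stop("no mRNA/transcript features in ", path)
  parent <- if ("Parent" %in% names(tx)) {
    vapply(tx$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(tx))
  tx_id <- if ("ID" %in% names(tx)) as.character(tx$ID) else
    paste0("tx", seq_len(nrow(tx)))
  gene_id <- ifelse(is.na(parent), tx_id, sub("^gene:", "", parent))
  has_exons <- if (any(md$type == "exon") && "Parent" %in% names(md)) {
    exon_parents <- unique(unlist(md$Parent[md$type == "exon"]))
    tx_id %in% exon_parents
  } else rep(TRUE, nrow(tx))
  if (any(!has_exons)) {
    message(sum(!has_exons), " transcript(s) without exon records skipped: ",
            paste(utils::head(tx_id[!has_exons], 3), collapse = ", "))
  }
  canonical <- if ("canonical" %in% names(tx)) {
    !is.na(tx$canonical) & tx$canonical %in% c("1", "true", "TRUE", "yes")
  } else rep(TRUE, nrow(tx))
  tibble::tibble(gene_id = gene_id[has_exons],
                 transcript_id = tx_id[has_exons],
                 contig = as.character(tx$seqnames)[has_exons],
                 strand = as.character(tx$strand)[has_exons],
                 start = tx$start[has_exons],
                 end = tx$end[has_exons],
                 canonical = canonical[has_exons])
}

#' Transcription start sites from transcript records
#'
#' One TSS per gene, at the first transcribed base of the canonical
#' transcript: the minimum coordinate on the plus strand, the maximum
#' coordinate on the minus strand. Input coordinates are 1-based
#' inclusive; the returned `tss` is 0-based.
#'
#' @param transcripts data frame with columns `gene_id`, `contig`,
#'   `strand` (+/-), `start`, `end`, and optionally `canonical`
#'   (logical; when present, only canonical rows are used and each gene
#'   must have exactly one).
#' @return tibble: `gene_id`, `contig`, `strand`, `tss` (0-based).
#' @examples
#' tx <- tibble::tibble(gene_id = "g1", contig = "chr1", strand = "+",
#'                      start = 1001, end = 2000)
#' extract_tss(tx)  # tss = 1000
#' @export
extract_tss <- function(transcripts) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(transcripts)))
  tx <- tibble::as_tibble(transcripts)
  if ("canonical" %in% names(tx)) tx <- dplyr::filter(tx, .data$canonical)
  if (!all(tx$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  n_per_gene <- table(tx$gene_id)
  multi <- names(n_per_gene)[n_per_gene > 1]
  if (length(multi)) {
    stop("gene(s) with more than one designated canonical transcript: ",
         paste(utils::head(multi, 3), collapse = ", "))
  }
  dplyr::transmute(tx,
                   gene_id = .data$gene_id,
                   contig = .data$contig,
                   strand = .data$strand,
                   tss = ifelse(.data$strand == "+",
                                .data$start - 1L, .data$end - 1L))
}

#' Extract upstream promoter sequences
#'
#' For a plus-strand gene with 0-based TSS `p`, the promoter is the
#' genomic interval `[p - length, p)`; for a minus-strand gene it is the
#' reverse complement of `(p, p + length]`. The TSS base itself is
#' excluded, and promoters are truncated at contig edges (reported via
#' the `truncated` column and a message).
#'
#' @param tss TSS table from [extract_tss()].
#' @param genome a named `Biostrings::DNAStringSet`, a named character
#'   vector of contig sequences, or a FASTA file path.
#' @param length promoter length in bases (default 1000).
#' @return tibble: `gene_id`, `sequence` (uppercase, gene orientation),
#'   `length`, `truncated`.
#' @export
extract_promoter <- function(tss, genome, length = 1000) {
  stopifnot(is.data.frame(tss),
            all(c("gene_id", "contig", "strand", "tss") %in% names(tss)))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(unique(tss$contig), names(genome))
  if (length(miss)) stop("contig(s) missing from the genome: ",
                         paste(miss, collapse = ", "))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    ctg <- tss$contig[i]; p <- tss$tss[i]; W <- clen[[ctg]]
    if (p < 0 || p >= W) stop("TSS of ", tss$gene_id[i], " outside contig ", ctg)
    if (tss$strand[i] == "+") {
      from <- max(p - length, 0)          # 0-based [from, p)
      seq_chr <- as.character(Biostrings::subseq(genome[[ctg]], from + 1, p))
      trunc <- p - length < 0
      if (p == 0) seq_chr <- ""
    } else {
      to <- min(p + length, W - 1)        # 0-based (p, to]
      seq_chr <- if (to > p) {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(genome[[ctg]], p + 2, to + 1)))
      } else ""
      trunc <- p + length > W - 1
    }
    tibble::tibble(gene_id = tss$gene_id[i],
                   sequence = toupper(seq_chr),
                   length = nchar(seq_chr),
                   truncated = trunc)
  })
  if (any(out$truncated)) {
    message(sum(out$truncated), " promoter(s) truncated at contig edges")
  }
  out
}
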