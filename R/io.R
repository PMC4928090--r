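# Plain-text I/O: all tables are TSV with a header row; counts have the
# gene id in the first column; promoters travel as FASTA.

#' Read a gene-level count table
#'
#' @param path TSV path: first column gene ids, then one column per
#'   sample.
#' @return tibble with `gene_id` first.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene_id"
  out
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `species`, `condition`,
#'   `replicate` (extra columns kept).
#' @return tibble.
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_samples(out)
  out
}

#' Read a one-to-one ortholog map
#'
#' @param path TSV whose first two columns are the species-A and
#'   species-B gene ids.
#' @return tibble with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(out) < 2) stop("ortholog map needs two columns")
  names(out)[1:2] <- c("gene_a", "gene_b")
  out
}

#' Read a gene-set annotation table
#'
#' @param path TSV with columns `term_id`, `gene_id` and optionally
#'   `term_name`.
#' @return tibble.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(out))) {
    stop("annotation needs columns term_id and gene_id")
  }
  out
}

#' Read promoters from a FASTA file
#'
#' @param path FASTA path; record names (up to the first whitespace) are
#'   taken as gene ids.
#' @return tibble: `gene_id`, `sequence`.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(gene_id = sub("\\s.*$", "", names(ss)),
                 sequence = toupper(as.character(ss)))
}

#' Write promoters to FASTA
#'
#' @param promoters tibble with `gene_id`, `sequence`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- promoters$gene_id
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
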