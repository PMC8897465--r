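#' Read and write BED intervals
#'
#' BED3 to BED6 files are read into a tibble of 0-based half-open intervals
#' (`chrom`, `start`, `end`, plus `name`, `score`, `strand` when present),
#' the convention used for TSS and enhancer annotation sets. Coordinates are
#' preserved verbatim; no 1-based shifting happens at this layer.
#'
#' @param path Path to a BED file (3 to 6 columns, tab-separated).
#' @return A tibble with columns `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3L || ncol(df) > 6L) {
    stop_format("BED file must have between 3 and 6 columns")
  }
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop_format("BED interval with end <= start")
  if (any(df$start < 0)) stop_format("BED interval with negative start")
  as_tibble(df)
}

#' @param intervals A tibble as returned by [read_bed()].
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("chrom", "start", "end"), "BED intervals")
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED is positional: truncate at the first absent optional column
  upto <- which(cumsum(!c("chrom", "start", "end", "name", "score", "strand")
                       %in% keep) == 0)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[upto]
  readr::write_tsv(intervals[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; the record key is the header token before the
#' first whitespace. Duplicate keys are an error.
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  keys <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(keys)) stop_format("duplicate FASTA record keys")
  setNames(toupper(as.character(seqs)), keys)
}

#' @param sequences Named character vector of sequences.
#' @param width Line-wrap width for the sequence body.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unname(toupper(sequences)))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
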