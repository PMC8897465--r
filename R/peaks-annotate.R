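#' Count motif occurrences within peaks
#'
#' Counts occurrences of a motif (default `GAGAG`, the GAGA-factor binding
#' element) inside each peak's sequence. Because (GA)n arrays are
#' self-overlapping, occurrences may share bases by default, and matches of
#' the reverse complement on the given strand are added when
#' `both_strands = TRUE`.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named character vector of chromosome sequences, as from
#'   [read_fasta()].
#' @param motif Motif string (default `"GAGAG"`).
#' @param both_strands Also count the reverse complement (default `TRUE`).
#' @param overlapping Allow occurrences to share bases (default `TRUE`).
#' @return The peak tibble with an added `motif_count` column; the mean count
#'   is attached as attribute `"mean_count"`.
#' @examples
#' g <- c(chr1 = "TTGAGAGAGTT")
#' peaks <- tibble::tibble(chrom = "chr1", start = 2L, end = 9L)
#' count_motif(peaks, g)
#' @export
count_motif <- function(peaks, genome, motif = "GAGAG",
                        both_strands = TRUE, overlapping = TRUE) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  motifs <- toupper(motif)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motifs)))
    motifs <- unique(c(motifs, rc))
  }
  counts <- vapply(seq_len(nrow(peaks)), function(i) {
    chr <- peaks$chrom[[i]]
    if (!chr %in% names(genome)) stop_input(paste0("chromosome not in genome: ", chr))
    seqlen <- nchar(genome[[chr]])
    if (peaks$end[[i]] > seqlen) {
      stop_input(sprintf("peak [%d,%d) exceeds %s length %d",
                         peaks$start[[i]], peaks$end[[i]], chr, seqlen))
    }
    subseq <- substr(genome[[chr]], peaks$start[[i]] + 1L, peaks$end[[i]])
    sum(vapply(motifs, count_occurrences, integer(1), text = subseq,
               overlapping = overlapping))
  }, integer(1))
  out <- mutate(as_tibble(peaks), motif_count = counts)
  attr(out, "mean_count") <- if (nrow(out)) mean(counts) else NA_real_
  out
}

count_occurrences <- function(pattern, text, overlapping = TRUE) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(text))
  if (overlapping) return(length(hits))
  # greedy left-to-right non-overlapping count
  starts <- Biostrings::start(hits)
  ends <- Biostrings::end(hits)
  count <- 0L
  last_end <- 0L
  for (k in seq_along(starts)) {
    if (starts[[k]] > last_end) {
      count <- count + 1L
      last_end <- ends[[k]]
    }
  }
  count
}

#' Annotate peaks as promoter, enhancer or other
#'
#' A peak is a promoter if it overlaps (>= 1 bp) the window of `tss_flank`
#' bp around a transcription start site; otherwise an enhancer if it
#' overlaps a supplied enhancer interval; otherwise other. Promoter takes
#' precedence when both apply, mirroring the ordered annotation rule.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param tss Tibble of 1-bp TSS intervals (`chrom`, `start`, `end`).
#' @param enhancers Tibble of enhancer intervals.
#' @param tss_flank Half-width in bp of the promoter window (default 100).
#' @return The peak tibble with an `annotation` column; the proportion table
#'   is attached as attribute `"proportions"` (a tibble that sums to 1).
#' @export
annotate_peaks <- function(peaks, tss, enhancers, tss_flank = 100) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  assert_cols(tss, c("chrom", "start", "end"), "tss")
  assert_cols(enhancers, c("chrom", "start", "end"), "enhancers")
  windows <- tibble(chrom = tss$chrom,
                    start = pmax(tss$start - tss_flank, 0L),
                    end = tss$start + tss_flank)
  is_prom <- overlaps_any(peaks, windows)
  is_enh <- overlaps_any(peaks, enhancers)
  label <- ifelse(is_prom, "promoter", ifelse(is_enh, "enhancer", "other"))
  out <- mutate(as_tibble(peaks), annotation = label)
  props <- out |>
    dplyr::count(.data$annotation) |>
    mutate(proportion = .data$n / sum(.data$n))
  attr(out, "proportions") <- props
  out
}

#' Metagene matrix of coverage around peak centers
#'
#' Extracts track values on the bin grid covering `[center - flank,
#' center + flank)` for each peak (center = `floor((start + end) / 2)`),
#' filling positions outside the track with 0, and averages columns into a
#' mean profile — the matrix behind center-anchored metagene plots such as
#' accessibility profiles over retained versus interphase-only peaks.
#'
#' @param track A [coverage_track()] tibble.
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param flank Half-window in bp (default 1000).
#' @return A list with `matrix` (peaks x positions), `positions` (bp offsets
#'   of bin starts relative to peak center) and `profile` (tibble of column
#'   means).
#' @export
metagene_matrix <- function(track, peaks, flank = 1000) {
  track <- validate_coverage_track(as_tibble(track))
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  bs <- track_bin_size(track)
  ncol_out <- as.integer(2 * flank / bs)
  lookup <- split(seq_len(nrow(track)), track$chrom)
  mat <- matrix(0, nrow = nrow(peaks), ncol = ncol_out)
  for (i in seq_len(nrow(peaks))) {
    center <- floor((peaks$start[[i]] + peaks$end[[i]]) / 2)
    first_bin_start <- floor((center - flank) / bs) * bs
    wanted <- first_bin_start + (seq_len(ncol_out) - 1L) * bs
    idx <- lookup[[peaks$chrom[[i]]]]
    if (!is.null(idx)) {
      pos <- match(wanted, track$start[idx])
      found <- !is.na(pos)
      mat[i, found] <- track$score[idx][pos[found]]
    }
  }
  positions <- (seq_len(ncol_out) - 1L) * bs - flank
  profile <- tibble(position = positions, mean_score = colMeans(mat))
  list(matrix = mat, positions = positions, profile = profile)
}

#' Plot a metagene profile
#'
#' @param metagene Result of [metagene_matrix()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(metagene) {
  ggplot(metagene$profile, aes(x = .data$position, y = .data$mean_score)) +
    geom_line() +
    labs(x = "position relative to peak center (bp)",
         y = "mean enrichment") +
    theme_minimal()
}
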