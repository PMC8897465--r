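#' Call enriched peaks on a binned coverage track
#'
#' The threshold/run/gap caller used for the GAF and H4K8ac ChIP tracks
#' (the algorithm of the Integrated Genome Browser's Thresholding view):
#'
#' 1. bins with value `>= threshold` are enriched;
#' 2. maximal runs of consecutive enriched bins become candidate regions;
#' 3. successive candidate regions on one chromosome separated by a gap of
#'    `<= max_gap` bp are merged;
#' 4. merged regions at least `min_run` bp long are reported, with
#'    boundaries on enriched-bin edges.
#'
#' The published settings are threshold 100 (GAF) or 22 (H4K8ac), minimum
#' run 50 bp and maximum gap 200 bp on 50-bp bins.
#'
#' @param track A [coverage_track()] tibble.
#' @param threshold Enrichment threshold; comparison is `>=`.
#' @param min_run Minimum merged-region length in bp (applied after merging).
#' @param max_gap Maximum gap in bp across which two enriched runs are merged.
#' @return A tibble of class `peak_set` with columns `chrom`, `start`, `end`,
#'   `max_value`, `n_enriched_bins`, carrying the calling parameters as the
#'   `"params"` attribute.
#' @examples
#' trk <- coverage_track("chr2L", c(10, 120, 130, 5, 5, 140, 150, 150, 10, 10))
#' call_peaks(trk, threshold = 100, min_run = 50, max_gap = 200)
#' @export
call_peaks <- function(track, threshold = 100, min_run = 50, max_gap = 200) {
  track <- validate_coverage_track(as_tibble(track))
  if (min_run < 0 || max_gap < 0) stop_input("`min_run` and `max_gap` must be >= 0")
  peaks <- track |>
    group_by(chrom) |>
    group_split() |>
    map(call_peaks_one_chrom, threshold = threshold,
        min_run = min_run, max_gap = max_gap) |>
    bind_rows()
  if (nrow(peaks) == 0L) {
    peaks <- tibble(chrom = character(), start = integer(), end = integer(),
                    max_value = double(), n_enriched_bins = integer())
  }
  peaks <- arrange(peaks, .data$chrom, .data$start)
  attr(peaks, "params") <- list(threshold = threshold, min_run = min_run,
                                max_gap = max_gap)
  class(peaks) <- c("peak_set", class(peaks))
  peaks
}

call_peaks_one_chrom <- function(sub, threshold, min_run, max_gap) {
  enriched <- sub$score >= threshold
  if (!any(enriched)) return(NULL)
  r <- rle(enriched)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- tibble(from = run_start[r$values], to = run_end[r$values])
  # merge runs whose genomic gap is <= max_gap bp
  merged_from <- runs$from[[1]]
  merged_to <- runs$to[[1]]
  out <- list()
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap_bp <- sub$start[[runs$from[[i]]]] - sub$end[[tail(merged_to, 1)[[1]]]]
      if (gap_bp <= max_gap) {
        merged_to[length(merged_to)] <- runs$to[[i]]
        merged_from[length(merged_from)] <- merged_from[length(merged_from)]
      } else {
        merged_from <- c(merged_from, runs$from[[i]])
        merged_to <- c(merged_to, runs$to[[i]])
      }
    }
  }
  regions <- tibble(
    chrom = sub$chrom[[1]],
    start = sub$start[merged_from],
    end = sub$end[merged_to],
    max_value = map_dbl(seq_along(merged_from), function(i) {
      max(sub$score[merged_from[[i]]:merged_to[[i]]])
    }),
    n_enriched_bins = map_int(seq_along(merged_from), function(i) {
      sum(enriched[merged_from[[i]]:merged_to[[i]]])
    })
  )
  filter(regions, .data$end - .data$start >= min_run)
}

#' Classify interphase peaks by mitotic retention
#'
#' An interphase peak overlapping any mitotic peak by at least 1 bp is
#' mitotically retained; interphase peaks with no such overlap are
#' interphase-only, and mitotic peaks overlapping no interphase peak are
#' mitosis-only.
#'
#' @param interphase,mitotic Peak tibbles (from [call_peaks()] or any tibble
#'   with `chrom`, `start`, `end`).
#' @return A tibble of all peaks with columns of the inputs plus `origin`
#'   (`"interphase"` or `"mitotic"`) and `class` (one of `"interphase_only"`,
#'   `"mitotically_retained"`, `"mitosis_only"`; mitotic peaks that overlap
#'   an interphase peak are labelled `"mitotically_retained"` from the
#'   mitotic side too and can be dropped with `origin == "interphase"`).
#' @export
classify_peaks <- function(interphase, mitotic) {
  assert_cols(interphase, c("chrom", "start", "end"), "interphase peaks")
  assert_cols(mitotic, c("chrom", "start", "end"), "mitotic peaks")
  i_hit <- overlaps_any(interphase, mitotic)
  m_hit <- overlaps_any(mitotic, interphase)
  inter <- as_tibble(interphase) |>
    mutate(origin = "interphase",
           class = ifelse(i_hit, "mitotically_retained", "interphase_only"))
  mito <- as_tibble(mitotic) |>
    mutate(origin = "mitotic",
           class = ifelse(m_hit, "mitotically_retained", "mitosis_only"))
  bind_rows(inter, mito)
}

# For each interval in `a`, does any interval of `b` on the same chromosome
# overlap it by >= 1 bp? Intervals are 0-based half-open.
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    if (!length(bi)) next
    qa <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    qb <- IRanges::IRanges(start = b$start[bi] + 1L, end = b$end[bi])
    hit[ai] <- IRanges::overlapsAny(qa, qb, minoverlap = 1L)
  }
  hit
}
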