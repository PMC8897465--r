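#' Rescale a coverage track to reads per million
#'
#' Multiplies every bin value by `1e6 / library_size`, the standard RPM
#' normalization applied before input subtraction and replicate averaging.
#'
#' @param track A [coverage_track()] tibble.
#' @param library_size Total mapped reads of the library (> 0).
#' @return A coverage track with rescaled scores.
#' @export
rescale_rpm <- function(track, library_size) {
  track <- validate_coverage_track(as_tibble(track))
  if (length(library_size) != 1L || !is.finite(library_size) || library_size <= 0) {
    stop_input("`library_size` must be a single positive number")
  }
  new_coverage_track(mutate(track, score = .data$score * 1e6 / library_size))
}

#' Subtract input (control) signal from a ChIP track
#'
#' Per-bin `chip - input`, reducing over-enrichment from biased sonication
#' and sequencing. Negative differences are clamped to zero by default since
#' downstream thresholds are positive.
#'
#' @param chip,input Coverage tracks on the same bin grid. Every chromosome
#'   of `chip` must be present in `input`.
#' @param floor_at_zero Clamp negative differences to 0 (default `TRUE`).
#' @return A coverage track of differences.
#' @export
subtract_input <- function(chip, input, floor_at_zero = TRUE) {
  chip <- validate_coverage_track(as_tibble(chip))
  input <- validate_coverage_track(as_tibble(input))
  if (track_bin_size(chip) != track_bin_size(input)) {
    stop_input("`chip` and `input` bin sizes differ")
  }
  missing <- setdiff(unique(chip$chrom), unique(input$chrom))
  if (length(missing)) {
    stop_input(paste0("chromosome(s) absent from input track: ",
                      paste(missing, collapse = ", ")))
  }
  joined <- left_join(chip, select(input, "chrom", "start", input_score = "score"),
                      by = c("chrom", "start"))
  if (anyNA(joined$input_score)) {
    stop_input("input track does not cover all chip bins")
  }
  diff <- joined$score - joined$input_score
  if (floor_at_zero) diff <- pmax(diff, 0)
  new_coverage_track(mutate(chip, score = diff))
}

#' Average replicate coverage tracks
#'
#' Per-bin arithmetic mean across biological replicates, producing the final
#' track used for peak calling.
#'
#' @param tracks List of coverage tracks on identical bin grids.
#' @return A coverage track of per-bin means.
#' @export
mean_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L || is.data.frame(tracks)) {
    stop_input("`tracks` must be a non-empty list of coverage tracks")
  }
  tracks <- map(tracks, function(t) validate_coverage_track(as_tibble(t)))
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) ||
        !all(t$chrom == ref$chrom) || !all(t$start == ref$start)) {
      stop_input("replicate tracks must share an identical bin grid")
    }
  }
  scores <- rowMeans(do.call(cbind, map(tracks, "score")))
  new_coverage_track(mutate(ref, score = scores))
}
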