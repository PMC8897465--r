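#' Build a binned coverage track
#'
#' A coverage track is a tibble with columns `chrom`, `start`, `end`, `score`
#' holding fixed-width, contiguous bins per chromosome in 0-based half-open
#' coordinates. This is the in-memory form of a fixedStep wiggle file binned
#' at a constant step (50 bp in the original tracks).
#'
#' @param chrom Chromosome name (scalar) or vector parallel to `values`.
#' @param values Numeric enrichment value per bin.
#' @param bin_size Bin width in bp (> 0).
#' @param origin 0-based start of the first bin.
#' @return A tibble of class `coverage_track` with one row per bin.
#' @examples
#' coverage_track("chr2L", c(1, 2, 5), bin_size = 50)
#' @export
coverage_track <- function(chrom, values, bin_size = 50L, origin = 0L) {
  if (bin_size <= 0) stop_input("`bin_size` must be > 0")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(values))
  if (length(chrom) != length(values)) {
    stop_input("`chrom` must be scalar or the same length as `values`")
  }
  out <- tibble(chrom = chrom, score = as.double(values)) |>
    group_by(chrom) |>
    mutate(start = origin + (row_number() - 1L) * as.integer(bin_size),
           end = .data$start + as.integer(bin_size)) |>
    ungroup() |>
    select("chrom", "start", "end", "score")
  new_coverage_track(out)
}

new_coverage_track <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("coverage_track", class(df))
  validate_coverage_track(df)
}

validate_coverage_track <- function(track) {
  assert_cols(track, c("chrom", "start", "end", "score"), "coverage track")
  if (nrow(track) == 0L) return(track)
  if (any(!is.finite(track$score))) stop_input("coverage values must be finite")
  widths <- unique(track$end - track$start)
  if (length(widths) != 1L || widths <= 0) {
    stop_format("all bins of a coverage track must share one positive bin size")
  }
  gaps <- track |>
    group_by(chrom) |>
    summarise(ok = all(diff(.data$start) == widths[[1]]) || n() == 1L)
  if (!all(gaps$ok)) stop_format("bins must be contiguous within a chromosome")
  track
}

track_bin_size <- function(track) {
  if (nrow(track) == 0L) return(NA_integer_)
  as.integer(track$end[[1]] - track$start[[1]])
}

#' Read a fixedStep wiggle file into a coverage track
#'
#' Only the fixedStep dialect is accepted: the original tracks are fixed
#' 50-bp bins, and accepting variableStep would require silent resampling.
#' Declared 1-based starts are converted to the 0-based half-open convention
#' used throughout the package. When a `span` field is present it must equal
#' `step` so that bins tile the chromosome.
#'
#' @param path Path to a fixedStep wiggle file.
#' @return A [coverage_track()] tibble.
#' @seealso [write_wiggle()] for the inverse.
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  lines <- str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (any(startsWith(lines, "variableStep"))) {
    stop_format("variableStep wiggle is not supported; tracks must be fixedStep")
  }
  decl_idx <- which(startsWith(lines, "fixedStep"))
  if (length(decl_idx) == 0L) stop_format("no fixedStep declaration found")
  bounds <- c(decl_idx, length(lines) + 1L)
  blocks <- map(seq_along(decl_idx), function(i) {
    decl <- lines[[decl_idx[[i]]]]
    body <- lines[seq2(decl_idx[[i]] + 1L, bounds[[i + 1L]] - 1L)]
    fields <- parse_wig_declaration(decl)
    values <- if (length(body)) as.double(body) else double(0)
    if (anyNA(values)) stop_format("non-numeric value line in wiggle body")
    tibble(chrom = fields$chrom,
           start = fields$start - 1L + (seq_along(values) - 1L) * fields$step,
           end = fields$start - 1L + seq_along(values) * fields$step,
           score = values,
           step = fields$step)
  })
  out <- bind_rows(blocks)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  score = double())
    return(new_coverage_track(out))
  }
  per_chrom <- out |> group_by(chrom) |> summarise(nstep = length(unique(.data$step)))
  if (any(per_chrom$nstep > 1L)) {
    stop_format("mixed step sizes within one chromosome")
  }
  new_coverage_track(select(out, -"step"))
}

parse_wig_declaration <- function(decl) {
  get_field <- function(name) {
    m <- str_match(decl, paste0(name, "=([^ \t]+)"))[, 2]
    m
  }
  chrom <- get_field("chrom")
  start <- suppressWarnings(as.integer(get_field("start")))
  step <- suppressWarnings(as.integer(get_field("step")))
  span <- suppressWarnings(as.integer(get_field("span")))
  if (is.na(chrom) || is.na(start) || is.na(step)) {
    stop_format(paste0("malformed fixedStep declaration: ", decl))
  }
  if (!is.na(span) && span != step) {
    stop_format("wiggle span must equal step so that bins tile")
  }
  list(chrom = chrom, start = start, step = step)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Write a coverage track as a fixedStep wiggle file
#'
#' Inverse of [read_wiggle()]: emits one fixedStep declaration block per
#' chromosome (sorted by name) with 1-based start coordinates.
#'
#' @param track A [coverage_track()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path) {
  track <- validate_coverage_track(as_tibble(track))
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in sort(unique(track$chrom))) {
    sub <- track[track$chrom == chr, ]
    step <- sub$end[[1]] - sub$start[[1]]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       chr, sub$start[[1]] + 1L, step, step), con)
    writeLines(format(sub$score, trim = TRUE, scientific = FALSE, digits = 15), con)
  }
  invisible(path)
}
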