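# Built-in defaults per pipeline stage. Keys mirror the function arguments
# they feed; values are the documented defaults of those functions.
config_defaults <- function() {
  list(
    peaks = list(threshold = 100, min_run = 50, max_gap = 200,
                 tss_flank = 100, motif = "GAGAG",
                 both_strands = TRUE, overlapping = TRUE,
                 floor_at_zero = TRUE, metagene_flank = 1000),
    frap = list(fit_frames = 1100, n_prebleach = 10, w = 0.83,
                frame_dt = 0.053, variant = "literal"),
    fcs = list(n_species = 2, s_param = 5, d_cal = 414),
    memory = list(n_states = 4, t0_mode = "pooled"),
    spots = list(log_sigma = 1, thr = 3, gauss_sigma = 2, eps = 1,
                 max_dist = 1.0)
  )
}

#' Load a run configuration file
#'
#' Reads a minimal TOML-style file — `[section]` headers naming pipeline
#' stages and `key = value` lines (numbers, booleans, quoted strings) — and
#' fills in the documented defaults for any key not given. Unknown keys
#' produce a warning, not an error; a known key whose value has the wrong
#' type is a configuration error.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return Nested named list: stage -> parameter -> value.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$peaks$threshold
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  if (is.null(path)) return(defaults)
  lines <- str_trim(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  section <- NULL
  user <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    m <- str_match(ln, "^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$")
    if (is.na(m[1, 1])) {
      abort(paste0("malformed configuration line: ", ln),
            class = "mitobook_config_error")
    }
    key <- m[1, 2]
    value <- parse_config_value(str_trim(m[1, 3]))
    sec <- section %||% "global"
    user[[sec]][[key]] <- value
  }
  merged <- defaults
  for (sec in names(user)) {
    if (!sec %in% names(defaults)) {
      warn(paste0("unknown configuration section: ", sec))
      merged[[sec]] <- user[[sec]]
      next
    }
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]])) {
        warn(sprintf("unknown configuration key %s.%s", sec, key))
      } else {
        old <- defaults[[sec]][[key]]
        new <- user[[sec]][[key]]
        if (is.numeric(old) && !is.numeric(new) ||
            is.character(old) && !is.character(new) ||
            is.logical(old) && !is.logical(new)) {
          abort(sprintf("configuration key %s.%s expects type %s",
                        sec, key, class(old)[[1]]),
                class = "mitobook_config_error")
        }
      }
      merged[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  merged
}

parse_config_value <- function(txt) {
  if (grepl('^".*"$', txt) || grepl("^'.*'$", txt)) {
    return(substr(txt, 2L, nchar(txt) - 1L))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  txt
}
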