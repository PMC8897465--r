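# Internal helpers shared across modules.

# Deterministic per-stream seed derivation: one user-facing seed fans out to
# independent substreams so adding a generator never shifts another's draws.
# Streams are named; the derived seed is a stable 31-bit hash of (seed, name).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chars <- utf8ToInt(paste0("s", stream))
  h <- as.double(seed %% .Machine$integer.max)
  for (ch in chars) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_stream_seed <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "mitobook_input_error")
  }
  invisible(df)
}

stop_input <- function(msg, class = "mitobook_input_error") {
  abort(msg, class = class)
}

stop_format <- function(msg) abort(msg, class = "mitobook_format_error")

stop_fit <- function(msg, diagnostics = NULL) {
  abort(msg, class = "mitobook_fit_error", diagnostics = diagnostics)
}
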