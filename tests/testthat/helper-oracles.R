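# Independent brute-force oracles. Each is written as a direct enumeration,
# sharing no code path with the package implementation it checks.

# Threshold/run/gap peak calling by explicit bin scanning.
oracle_call_peaks <- function(track, threshold, min_run, max_gap) {
  out <- list()
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    enriched_idx <- which(sub$score >= threshold)
    if (!length(enriched_idx)) next
    # maximal runs of consecutive enriched bins
    runs <- list()
    run_start <- enriched_idx[[1]]
    prev <- enriched_idx[[1]]
    for (i in enriched_idx[-1]) {
      if (i != prev + 1L) {
        runs[[length(runs) + 1L]] <- c(run_start, prev)
        run_start <- i
      }
      prev <- i
    }
    runs[[length(runs) + 1L]] <- c(run_start, prev)
    # merge across gaps <= max_gap bp
    merged <- list(runs[[1]])
    if (length(runs) > 1L) {
      for (r in runs[-1]) {
        last <- merged[[length(merged)]]
        gap <- sub$start[[r[[1]]]] - sub$end[[last[[2]]]]
        if (gap <= max_gap) {
          merged[[length(merged)]] <- c(last[[1]], r[[2]])
        } else {
          merged[[length(merged) + 1L]] <- r
        }
      }
    }
    for (m in merged) {
      s <- sub$start[[m[[1]]]]
      e <- sub$end[[m[[2]]]]
      if (e - s >= min_run) {
        idx <- m[[1]]:m[[2]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = s, end = e,
          max_value = max(sub$score[idx]),
          n_enriched_bins = sum(sub$score[idx] >= threshold))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      max_value = double(), n_enriched_bins = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

# Sliding-window motif counting with explicit character comparison.
oracle_count_motif <- function(sequence, motif = "GAGAG", both_strands = TRUE,
                               overlapping = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  count_one <- function(seq, pat) {
    n <- nchar(seq); m <- nchar(pat)
    if (m > n) return(0L)
    cnt <- 0L
    i <- 1L
    while (i <= n - m + 1L) {
      if (substr(seq, i, i + m - 1L) == pat) {
        cnt <- cnt + 1L
        i <- if (overlapping) i + 1L else i + m
      } else {
        i <- i + 1L
      }
    }
    cnt
  }
  total <- count_one(sequence, motif)
  if (both_strands && revcomp(motif) != motif) {
    total <- total + count_one(sequence, revcomp(motif))
  }
  total
}

# O(n^2) pairwise half-open overlap classification.
oracle_classify <- function(interphase, mitotic) {
  ov <- function(a, b) a$chrom == b$chrom && a$start < b$end && b$start < a$end
  i_hit <- vapply(seq_len(nrow(interphase)), function(i) {
    any(vapply(seq_len(nrow(mitotic)), function(j) {
      ov(interphase[i, ], mitotic[j, ])
    }, logical(1)))
  }, logical(1))
  m_hit <- vapply(seq_len(nrow(mitotic)), function(j) {
    any(vapply(seq_len(nrow(interphase)), function(i) {
      ov(interphase[i, ], mitotic[j, ])
    }, logical(1)))
  }, logical(1))
  list(retained = sum(i_hit), interphase_only = sum(!i_hit),
       mitosis_only = sum(!m_hit))
}

# Product-limit estimator coded directly from its definition.
oracle_km <- function(time, status) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]
  ev_times <- sort(unique(time[status == 1]))
  S <- 1
  out_s <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    tk <- ev_times[[k]]
    n_risk <- sum(time >= tk)
    d <- sum(time == tk & status == 1)
    S <- S * (1 - d / n_risk)
    out_s[[k]] <- S
  }
  data.frame(time = ev_times, surv = out_s)
}

# Brute-force mutual nearest neighbours on physical coordinates.
oracle_mnn <- function(A, B, voxel_xy, voxel_z, max_dist) {
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(data.frame(index_a = integer(), index_b = integer(),
                      distance = double()))
  }
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dmat[i, j] <- sqrt(((A$x[[i]] - B$x[[j]]) * voxel_xy)^2 +
                         ((A$y[[i]] - B$y[[j]]) * voxel_xy)^2 +
                         ((A$z[[i]] - B$z[[j]]) * voxel_z)^2)
    }
  }
  pairs <- list()
  for (i in seq_len(nrow(A))) {
    j <- which.min(dmat[i, ])
    if (which.min(dmat[, j]) == i && dmat[i, j] <= max_dist) {
      pairs[[length(pairs) + 1L]] <- data.frame(index_a = i, index_b = j,
                                                distance = dmat[i, j])
    }
  }
  if (!length(pairs)) {
    return(data.frame(index_a = integer(), index_b = integer(),
                      distance = double()))
  }
  do.call(rbind, pairs)
}

# Random coverage track for property tests.
random_track <- function(n_bins = 200, bin_size = 50, chrom = "chrS",
                         high_frac = 0.2, threshold = 100) {
  vals <- abs(rnorm(n_bins, sd = 20))
  hot <- runif(n_bins) < high_frac
  vals[hot] <- threshold + abs(rnorm(sum(hot), sd = 80))
  coverage_track(chrom, vals, bin_size = bin_size)
}
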