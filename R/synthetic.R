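# Seeded generators emulating every input kind the pipeline consumes. Each
# returns list(data = ..., truth = ...) and is a deterministic function of
# its seed; seeds fan out to named substreams (see derive_seed) so adding a
# generator never shifts another's draws.

#' Generate synthetic FRAP traces
#'
#' Normalized recoveries are drawn from [frap_model()] with the given
#' generative parameters plus i.i.d. Gaussian noise; pre-bleach frames sit
#' at 1 plus noise. Raw `i_bleach`/`i_unbleach`/`i_outside` channels are
#' emitted such that [frap_normalize()] reproduces the normalized curve
#' exactly in the noiseless case. Acquisition defaults mirror the original
#' protocol: one frame every 53 ms, 1200 frames, bleach after 10 frames.
#'
#' @param params Named list of generative parameters
#'   (`K`, `M`, `tau`, `F_eq`, `k_off`, `F_inf`, optional `variant`).
#' @param n_traces Number of nuclei.
#' @param noise_sd Gaussian noise standard deviation on the normalized scale.
#' @param frame_dt Frame interval (s, default 0.053).
#' @param n_frames Total frames per trace (default 1200).
#' @param n_prebleach Pre-bleach frames (default 10).
#' @param seed Seed (optional).
#' @return `list(traces, truth)`; `traces` is a long tibble with columns
#'   `nucleus_id`, `time`, `i_bleach`, `i_unbleach`, `i_outside`.
#' @export
gen_frap_traces <- function(params, n_traces = 1, noise_sd = 0,
                            frame_dt = 0.053, n_frames = 1200,
                            n_prebleach = 10, seed = NULL) {
  variant <- params$variant %||% "literal"
  with_stream_seed(seed, "frap", {
    times <- (seq_len(n_frames) - 1L) * frame_dt
    post <- seq(n_prebleach + 1L, n_frames)
    t_post <- times[post] - times[post][[1]]
    model <- frap_model(t_post, K = params$K, M = params$M %||% 1,
                        tau = params$tau, F_eq = params$F_eq,
                        k_off = params$k_off, F_inf = params$F_inf %||% 1,
                        variant = variant)
    i_out <- 20
    i_unbl <- 120
    traces <- map(seq_len(n_traces), function(i) {
      target <- c(rep(1, n_prebleach), model) + rnorm(n_frames, sd = noise_sd)
      tibble(nucleus_id = sprintf("nucleus_%03d", i),
             time = times,
             i_bleach = i_out + target * (i_unbl - i_out),
             i_unbleach = i_unbl,
             i_outside = i_out)
    }) |> bind_rows()
    list(traces = traces,
         truth = list(stage = "frap", parameters = params,
                      noise_sd = noise_sd, n_prebleach = n_prebleach,
                      frame_dt = frame_dt))
  })
}

#' Generate synthetic FCS autocorrelation curves
#'
#' Closed-form [acf_model()] curves on a log-spaced lag grid with
#' multiplicative Gaussian noise on the correlation amplitude `G - 1`.
#'
#' @param params Named list (`N`, `T_trip`, `tau_T`, `f`, `tau_d`,
#'   `s_param`, `G_inf`).
#' @param lags Lag grid (s); default 128 log-spaced points in
#'   `[1e-6, 1]`.
#' @param noise_sd Relative noise level on `G - 1` (default 0).
#' @param n_curves Number of curves.
#' @param seed Seed (optional).
#' @return `list(curves, truth)`; `curves` has columns `curve_id`, `lag`, `G`.
#' @export
gen_acf <- function(params, lags = NULL, noise_sd = 0, n_curves = 1,
                    seed = NULL) {
  lags <- lags %||% exp(seq(log(1e-6), log(1), length.out = 128))
  with_stream_seed(seed, "fcs", {
    clean <- acf_model(lags, N = params$N, T_trip = params$T_trip %||% 0,
                       tau_T = params$tau_T %||% 1e-6, f = params$f,
                       tau_d = params$tau_d, s_param = params$s_param %||% 5,
                       G_inf = params$G_inf %||% 0)
    curves <- map(seq_len(n_curves), function(i) {
      noisy <- 1 + (clean - 1) * (1 + rnorm(length(lags), sd = noise_sd))
      tibble(curve_id = sprintf("curve_%03d", i), lag = lags, G = noisy)
    }) |> bind_rows()
    list(curves = curves,
         truth = list(stage = "fcs", parameters = params, noise_sd = noise_sd))
  })
}

#' Brownian-dynamics oracle for the single-species ACF
#'
#' Simulates point emitters diffusing in a periodic box through a 3D
#' Gaussian detection volume (1/e^2 radii `w_xy`, `w_z = s_param * w_xy`),
#' records the total intensity trace, and autocorrelates it directly. This
#' is an independent physical check of the single-species autocorrelation
#' shape: it shares no code with [acf_model()].
#'
#' @param D Diffusion coefficient (um^2/s).
#' @param w_xy Lateral waist (um).
#' @param s_param Structure parameter.
#' @param n_particles Number of emitters.
#' @param duration Trace duration (s).
#' @param dt Time step (s).
#' @param box_factor Box half-width in units of `w_xy` (default 6).
#' @param seed Seed (optional).
#' @return Tibble with columns `lag` and `G` (normalized so
#'   `G(inf) -> 1`).
#' @export
gen_acf_brownian <- function(D, w_xy = 0.2, s_param = 5, n_particles = 200,
                             duration = 20, dt = 5e-4, box_factor = 6,
                             seed = NULL) {
  with_stream_seed(seed, "fcs_brownian", {
    n_steps <- as.integer(round(duration / dt))
    half <- box_factor * w_xy
    w_z <- s_param * w_xy
    sdstep <- sqrt(2 * D * dt)
    wrap <- function(u) ((u + half) %% (2 * half)) - half
    x <- runif(n_particles, -half, half)
    y <- runif(n_particles, -half, half)
    z_half <- max(half, 3 * w_z)
    z <- runif(n_particles, -z_half, z_half)
    intensity <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      x <- wrap(x + rnorm(n_particles, sd = sdstep))
      y <- wrap(y + rnorm(n_particles, sd = sdstep))
      z <- ((z + rnorm(n_particles, sd = sdstep) + z_half) %% (2 * z_half)) - z_half
      intensity[[s]] <- sum(exp(-2 * (x^2 + y^2) / w_xy^2 - 2 * z^2 / w_z^2))
    }
    ac <- acf_fft(intensity - mean(intensity))
    G <- 1 + ac / mean(intensity)^2
    lag_idx <- unique(round(exp(seq(log(1), log(n_steps / 10), length.out = 60))))
    tibble(lag = lag_idx * dt, G = G[lag_idx + 1L])
  })
}

# Remove every GAGAG / CTCTC occurrence from a sequence by point mutation,
# so planted arrays are the only motif instances.
scrub_motif <- function(s) {
  repeat {
    s2 <- gsub("GAGAG", "GATAG", s, fixed = TRUE)
    s2 <- gsub("CTCTC", "CTATC", s2, fixed = TRUE)
    if (identical(s2, s)) return(s)
    s <- s2
  }
}

# Unnormalized autocovariance via FFT (biased estimator, lag 0..n-1).
acf_fft <- function(x) {
  n <- length(x)
  padded <- c(x, numeric(n))
  f <- fft(padded)
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / length(padded)
  ac[seq_len(n)] / n
}

#' Generate synthetic binned coverage, genome and truth peaks
#'
#' Background bins are |Normal| low-level noise; planted peaks are
#' rectangular enrichment blocks with jittered heights above a target
#' threshold. The accompanying genome is random ACGT with (GA)k arrays
#' planted inside designated peaks, so motif counts have a known truth. An
#' input track with matching background statistics is produced alongside the
#' ChIP track.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bins.
#' @param bin_size Bin width in bp (default 50).
#' @param n_peaks Planted peaks per chromosome.
#' @param peak_height_range Range of planted peak heights (above threshold).
#' @param peak_width_bins Range of planted peak widths in bins.
#' @param background_noise SD of the |Normal| background.
#' @param motif_arrays_per_peak (GA)k arrays planted per peak.
#' @param motif_array_k Number of GA dinucleotide repeats per array.
#' @param seed Seed (optional).
#' @return `list(chip, input, genome, truth)`: two coverage tracks, a named
#'   character genome and a truth tibble (`chrom`, `start`, `end`, `height`,
#'   `motif_count` of planted forward GAGAG occurrences).
#' @export
gen_coverage_and_genome <- function(n_chrom = 1, chrom_len = 2000,
                                    bin_size = 50, n_peaks = 10,
                                    peak_height_range = c(150, 300),
                                    peak_width_bins = c(3, 10),
                                    background_noise = 5,
                                    motif_arrays_per_peak = 2,
                                    motif_array_k = 4,
                                    seed = NULL) {
  with_stream_seed(seed, "coverage", {
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    chip_list <- list()
    input_list <- list()
    genome <- character()
    truth <- list()
    for (chr in chroms) {
      bg <- abs(rnorm(chrom_len, sd = background_noise))
      values <- bg
      # slotted placement: the guard gap between planted peaks must exceed
      # the caller's default 200-bp merge distance so truths stay distinct
      max_w <- peak_width_bins[[2]]
      guard <- as.integer(ceiling(250 / bin_size))
      slot_size <- max_w + guard
      n_slots <- chrom_len %/% slot_size
      if (n_slots < n_peaks) {
        abort("too many peaks for the chromosome length",
              class = "mitobook_generation_error")
      }
      slots <- sort(sample.int(n_slots, n_peaks))
      chrom_seq <- paste(sample(c("A", "C", "G", "T"), chrom_len * bin_size,
                                replace = TRUE), collapse = "")
      chrom_seq <- scrub_motif(chrom_seq)  # no accidental GAGAG/CTCTC
      for (si in seq_along(slots)) {
        w <- sample(seq(peak_width_bins[[1]], peak_width_bins[[2]]), 1L)
        first <- (slots[[si]] - 1L) * slot_size + 2L
        bins <- seq(first, first + w - 1L)
        h <- runif(1, peak_height_range[[1]], peak_height_range[[2]])
        values[bins] <- h + abs(rnorm(w, sd = background_noise))
        start_bp <- (first - 1L) * bin_size
        end_bp <- (first - 1L + w) * bin_size
        # plant T-flanked (GA)k arrays inside the peak
        array_str <- strrep("GA", motif_array_k)
        arr_len <- nchar(array_str)
        n_arrays <- motif_arrays_per_peak
        for (ai in seq_len(n_arrays)) {
          pos <- start_bp + 10L + (ai - 1L) * (arr_len + 10L)
          substr(chrom_seq, pos, pos + arr_len + 1L) <-
            paste0("T", array_str, "T")
        }
        # a (GA)k array holds k - 2 overlapping GAGAG sites (forward only)
        motif_per_array <- max(motif_array_k - 2L, 0L)
        truth[[length(truth) + 1L]] <- tibble(
          chrom = chr, start = start_bp, end = end_bp, height = h,
          motif_count = n_arrays * motif_per_array)
      }
      chip_list[[chr]] <- coverage_track(chr, values, bin_size = bin_size)
      input_list[[chr]] <- coverage_track(
        chr, abs(rnorm(chrom_len, sd = background_noise)), bin_size = bin_size)
      genome[[chr]] <- chrom_seq
    }
    list(chip = new_coverage_track(bind_rows(chip_list)),
         input = new_coverage_track(bind_rows(input_list)),
         genome = genome,
         truth = bind_rows(truth))
  })
}

#' Generate a synthetic 3D image stack with planted Gaussian spots
#'
#' Sum of isotropic 3D Gaussians at random, well-separated positions plus
#' Gaussian noise, clipped at zero — a stand-in for MS2/FISH spot stacks.
#'
#' @param shape `(z, y, x)` dimensions.
#' @param n_spots Number of planted spots.
#' @param spot_sigma Spot Gaussian sigma in voxels.
#' @param peak_intensity Peak amplitude of each spot.
#' @param noise_sd Additive Gaussian noise SD.
#' @param voxel_xy,voxel_z Voxel sizes in um.
#' @param seed Seed (optional).
#' @return `list(stack, truth)`; `truth` is a tibble of planted centers in
#'   voxel units (`z`, `y`, `x`).
#' @export
gen_image_stack <- function(shape = c(16, 64, 64), n_spots = 10,
                            spot_sigma = 1.5, peak_intensity = 100,
                            noise_sd = 0, voxel_xy = 0.1, voxel_z = 0.3,
                            seed = NULL) {
  with_stream_seed(seed, "stack", {
    # per-axis margins, clamped so thin stacks remain usable
    margin <- pmin(ceiling(4 * spot_sigma), floor((shape - 1) / 2))
    min_sep <- 4 * spot_sigma
    centers <- matrix(numeric(0), ncol = 3)
    tries <- 0L
    while (nrow(centers) < n_spots) {
      tries <- tries + 1L
      if (tries > 2000L) {
        abort("could not place spots with the required separation",
              class = "mitobook_generation_error")
      }
      cand <- c(runif(1, margin[[1]] + 1, shape[[1]] - margin[[1]]),
                runif(1, margin[[2]] + 1, shape[[2]] - margin[[2]]),
                runif(1, margin[[3]] + 1, shape[[3]] - margin[[3]]))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep)) {
        centers <- rbind(centers, cand)
      }
    }
    stack <- array(0, shape)
    zz <- seq_len(shape[[1]])
    yy <- seq_len(shape[[2]])
    xx <- seq_len(shape[[3]])
    for (i in seq_len(nrow(centers))) {
      gz <- exp(-(zz - centers[i, 1])^2 / (2 * spot_sigma^2))
      gy <- exp(-(yy - centers[i, 2])^2 / (2 * spot_sigma^2))
      gx <- exp(-(xx - centers[i, 3])^2 / (2 * spot_sigma^2))
      stack <- stack + peak_intensity * outer(outer(gz, gy), gx)
    }
    if (noise_sd > 0) {
      stack <- stack + array(rnorm(length(stack), sd = noise_sd), shape)
      stack[stack < 0] <- 0
    }
    truth <- tibble(z = centers[, 1], y = centers[, 2], x = centers[, 3])
    list(stack = stack, truth = truth)
  })
}

#' Generate a lineage-annotated activation table
#'
#' Two subpopulations of nuclei — daughters of transcriptionally active and
#' of inactive mothers — with waiting times drawn from the linear
#' irreversible chain via [simulate_chain()], censored at movie end.
#'
#' @param n_active,n_inactive Nuclei per subpopulation.
#' @param p_act,p_in Jump-count probabilities per subpopulation.
#' @param tau_act,tau_in OFF-state lifetimes (s).
#' @param T0 Deterministic lag (s).
#' @param t_end Movie end (s).
#' @param seed Seed (optional).
#' @return `list(records, truth)`.
#' @export
gen_lineage <- function(n_active = 100, n_inactive = 100,
                        p_act = c(0.3, 0.4, 0.3), tau_act = 100,
                        p_in = c(0.3, 0.4, 0.3), tau_in = 200,
                        T0 = 120, t_end = 2400, seed = NULL) {
  act <- simulate_chain(p_act, tau_act, n_active, T0 = T0, t_end = t_end,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, "lineage_a"),
                        movie_id = "movie_1", mother_state = "active")
  ina <- simulate_chain(p_in, tau_in, n_inactive, T0 = T0, t_end = t_end,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, "lineage_i"),
                        movie_id = "movie_1", mother_state = "inactive")
  list(records = bind_rows(act, ina),
       truth = list(stage = "lineage",
                    active = list(p = p_act, tau = tau_act,
                                  a = sum(seq_along(p_act) * p_act)),
                    inactive = list(p = p_in, tau = tau_in,
                                    a = sum(seq_along(p_in) * p_in)),
                    T0 = T0, t_end = t_end))
}
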