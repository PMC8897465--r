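#' Detect 3D spots by Laplacian-of-Gaussian filtering
#'
#' The filtered image is the negated LoG of the raw stack (so bright blobs
#' become maxima), thresholded at `mu + thr * sigma` where `mu` and `sigma`
#' are the mean and standard deviation of the filtered frame — `thr` is the
#' only user choice and is common across frames of a movie. Voxels above
#' threshold are grouped into 26-connected components; intensities and
#' intensity-weighted centers of mass are read from the *raw* voxel values
#' inside each component, the masked-with-raw-data convention.
#'
#' @param stack 3D `(z, y, x)` or 4D `(t, z, y, x)` nonnegative array.
#' @param log_sigma LoG Gaussian sigma in voxels (default 1).
#' @param thr Threshold in filtered-image standard deviations (default 3).
#' @param voxel_xy,voxel_z Voxel sizes in um (defaults 1), carried to the
#'   spot table for downstream physical-distance computations.
#' @return A tibble (class `spot_set`) with one row per spot: `frame`, `z`,
#'   `y`, `x` (voxel-unit centers of mass), `z_um`, `y_um`, `x_um`,
#'   `total_intensity`, `n_voxels`. Voxel sizes are carried as attributes
#'   `voxel_xy`, `voxel_z`.
#' @export
detect_spots <- function(stack, log_sigma = 1, thr = 3,
                         voxel_xy = 1, voxel_z = 1) {
  nd <- length(dim(stack))
  if (!nd %in% c(3L, 4L)) stop_input("`stack` must be a 3D or 4D array")
  if (length(stack) == 0L) stop_input("empty image")
  frames <- if (nd == 3L) list(stack) else {
    map(seq_len(dim(stack)[[1]]), function(i) {
      arr <- stack[i, , , , drop = TRUE]
      dim(arr) <- dim(stack)[-1]
      arr
    })
  }
  out <- imap(frames, function(frame, fi) {
    filtered <- log_filter_3d(frame, log_sigma)
    mu <- mean(filtered)
    sig <- sd(as.vector(filtered))
    if (!is.finite(sig) || sig == 0) return(NULL)  # flat frame: nothing to call
    mask <- filtered >= mu + thr * sig
    labels <- label_components_3d(mask)
    n_comp <- max(labels)
    if (n_comp == 0L) return(NULL)
    comps <- split(which(labels > 0L), labels[labels > 0L])
    map(comps, function(vox) {
      d <- dim(frame)
      v0 <- vox - 1L
      z <- v0 %% d[[1]] + 1L
      y <- (v0 %/% d[[1]]) %% d[[2]] + 1L
      x <- v0 %/% (d[[1]] * d[[2]]) + 1L
      raw_vals <- frame[vox]
      w <- if (sum(raw_vals) == 0) rep(1, length(vox)) else raw_vals
      tibble(frame = fi, z = sum(w * z) / sum(w), y = sum(w * y) / sum(w),
             x = sum(w * x) / sum(w),
             total_intensity = sum(raw_vals), n_voxels = length(vox))
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), z = double(), y = double(), x = double(),
                  total_intensity = double(), n_voxels = integer())
  }
  out <- mutate(out, z_um = .data$z * voxel_z, y_um = .data$y * voxel_xy,
                x_um = .data$x * voxel_xy)
  attr(out, "voxel_xy") <- voxel_xy
  attr(out, "voxel_z") <- voxel_z
  class(out) <- c("spot_set", class(out))
  out
}

#' Segment nuclei by log-Otsu thresholding
#'
#' The stack is Gaussian-smoothed, log-transformed (the log compresses
#' non-homogeneous intensity inside nuclei), and thresholded per z-slice
#' with Otsu's method, the threshold adapting to each slice. Constant
#' slices yield an empty mask with a warning.
#'
#' @param stack 3D `(z, y, x)` array.
#' @param gauss_sigma Smoothing sigma in voxels (default 2).
#' @param eps Offset added before the log (default 1 intensity unit).
#' @param per `"slice"` (default) applies Otsu per z-slice; `"stack"` uses
#'   one global threshold.
#' @return Logical array of the same shape.
#' @export
segment_nuclei <- function(stack, gauss_sigma = 2, eps = 1,
                           per = c("slice", "stack")) {
  per <- match.arg(per)
  if (length(dim(stack)) != 3L) stop_input("`stack` must be a 3D array")
  if (gauss_sigma <= 0) stop_input("`gauss_sigma` must be > 0")
  smoothed <- gaussian_filter_3d(stack, gauss_sigma)
  L <- log(smoothed + eps)
  mask <- array(FALSE, dim(L))
  if (per == "stack") {
    thr <- otsu_threshold(as.vector(L))
    if (is.na(thr)) {
      warn("constant stack; returning empty mask")
      return(mask)
    }
    return(L >= thr)
  }
  flat <- integer(0)
  for (zi in seq_len(dim(L)[[1]])) {
    slice <- L[zi, , ]
    thr <- otsu_threshold(as.vector(slice))
    if (is.na(thr)) {
      flat <- c(flat, zi)
      next
    }
    mask[zi, , ] <- slice >= thr
  }
  if (length(flat)) {
    warn(sprintf("constant slice(s) %s; empty mask there",
                 paste(flat, collapse = ", ")))
  }
  mask
}

#' Keep only spots inside nuclei
#'
#' A spot is kept when its center voxel (rounded) falls inside the nuclei
#' mask.
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param mask Logical array from [segment_nuclei()], same shape as the
#'   stack the spots were detected in.
#' @return Filtered spot tibble.
#' @export
filter_spots_in_nuclei <- function(spots, mask) {
  assert_cols(spots, c("z", "y", "x"), "spots")
  d <- dim(mask)
  if (length(d) != 3L) stop_input("`mask` must be a 3D array")
  keep <- map_int(seq_len(nrow(spots)), function(i) {
    z <- round(spots$z[[i]]); y <- round(spots$y[[i]]); x <- round(spots$x[[i]])
    if (z < 1 || z > d[[1]] || y < 1 || y > d[[2]] || x < 1 || x > d[[3]]) {
      return(0L)
    }
    as.integer(mask[z, y, x])
  })
  spots[keep == 1L, ]
}

#' Mutual nearest-neighbour spot pairs with anisotropic distances
#'
#' Pairs spots of two channels (two DNA-FISH probes) by mutual nearest
#' neighbours on physical coordinates: x and y scaled by `voxel_xy`, z by
#' `voxel_z` (the z pixel size differs from xy). A pair `(a, b)` is kept iff
#' `b` is `a`'s nearest neighbour in `B` and `a` is `b`'s nearest in `A`;
#' aberrant pairs farther apart than `max_dist` (1 um by default) are
#' discarded. Ties break to the lowest index.
#'
#' @param A,B Spot tibbles with voxel-unit `z`, `y`, `x` columns.
#' @param voxel_xy,voxel_z Voxel sizes in um (defaults taken from the `A`
#'   attributes when present, else 1).
#' @param max_dist Maximum retained pair distance in um (default 1).
#' @return Tibble with `index_a`, `index_b` and `distance` (um).
#' @export
mutual_nearest_pairs <- function(A, B, voxel_xy = NULL, voxel_z = NULL,
                                 max_dist = 1.0) {
  assert_cols(A, c("z", "y", "x"), "spot set A")
  assert_cols(B, c("z", "y", "x"), "spot set B")
  voxel_xy <- voxel_xy %||% attr(A, "voxel_xy") %||% 1
  voxel_z <- voxel_z %||% attr(A, "voxel_z") %||% 1
  empty <- tibble(index_a = integer(), index_b = integer(), distance = double())
  if (nrow(A) == 0L || nrow(B) == 0L) return(empty)
  pa <- cbind(A$x * voxel_xy, A$y * voxel_xy, A$z * voxel_z)
  pb <- cbind(B$x * voxel_xy, B$y * voxel_xy, B$z * voxel_z)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1L, which.min)   # lowest index on ties
  nn_ba <- apply(d2, 2L, which.min)
  ia <- which(nn_ba[nn_ab] == seq_len(nrow(A)))
  out <- tibble(index_a = ia, index_b = nn_ab[ia],
                distance = sqrt(d2[cbind(ia, nn_ab[ia])]))
  filter(out, .data$distance <= max_dist)
}

#' Background-normalized transcription-site intensities
#'
#' Transcription-site intensity is the sum of raw intensities over the
#' spot's voxels; it is divided by the movie background, the mean of the
#' mean raw intensities of several regions (six in the original analysis)
#' taken outside any transcriptional spot.
#'
#' @param spots Spot tibble with a `total_intensity` column.
#' @param background_rois List of numeric vectors/arrays of raw voxel values,
#'   one per background region.
#' @return The spot tibble with an added `intensity_norm` column; the
#'   background value is attached as attribute `"background"`.
#' @export
spot_intensity_normalized <- function(spots, background_rois) {
  assert_cols(spots, "total_intensity", "spots")
  if (length(background_rois) == 0L) stop_input("need at least one background region")
  background <- mean(map_dbl(background_rois, function(r) mean(as.numeric(r))))
  if (background == 0) stop_input("zero background")
  out <- mutate(as_tibble(spots), intensity_norm = .data$total_intensity / background)
  attr(out, "background") <- background
  out
}

#' Remove spots persisting from mitosis (keep de novo spots)
#'
#' Spots detected during mitosis (e.g. retained MS2 foci) are projected
#' forward: any post-mitotic spot within `radius` (um, physical distance) of
#' a mitotic spot position is removed, so that only de novo appearing
#' punctae remain for the memory analysis. Frames up to and including the
#' mitosis window are returned unchanged.
#'
#' @param spots Spot tibble with `frame`, `z`, `y`, `x`.
#' @param mitosis_frames Length-2 vector `(first, last)` mitotic frame.
#' @param radius Removal radius in um (default 0.5).
#' @param voxel_xy,voxel_z Voxel sizes in um (defaults from attributes).
#' @return Filtered spot tibble.
#' @export
filter_de_novo <- function(spots, mitosis_frames, radius = 0.5,
                           voxel_xy = NULL, voxel_z = NULL) {
  assert_cols(spots, c("frame", "z", "y", "x"), "spots")
  voxel_xy <- voxel_xy %||% attr(spots, "voxel_xy") %||% 1
  voxel_z <- voxel_z %||% attr(spots, "voxel_z") %||% 1
  mito <- filter(as_tibble(spots),
                 .data$frame >= mitosis_frames[[1]],
                 .data$frame <= mitosis_frames[[2]])
  if (nrow(mito) == 0L) return(spots)
  post_idx <- which(spots$frame > mitosis_frames[[2]])
  if (!length(post_idx)) return(spots)
  pm <- cbind(mito$x * voxel_xy, mito$y * voxel_xy, mito$z * voxel_z)
  pp <- cbind(spots$x[post_idx] * voxel_xy, spots$y[post_idx] * voxel_xy,
              spots$z[post_idx] * voxel_z)
  d2 <- outer(rowSums(pp^2), rowSums(pm^2), "+") - 2 * pp %*% t(pm)
  near <- apply(d2, 1L, min) <= radius^2
  drop_idx <- post_idx[near]
  if (length(drop_idx)) spots[-drop_idx, ] else spots
}
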