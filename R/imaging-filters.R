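# Separable 3D Gaussian convolution and a discrete Laplacian, the two
# primitives behind LoG spot detection and nuclei smoothing. Arrays are
# (z, y, x); borders replicate the edge voxel (nearest mode).

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  idx <- function(n, shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  for (j in seq_along(kernel)) {
    shift <- j - 1L - half
    src <- idx(d[[axis]], shift)
    slice_src <- switch(axis,
                        arr[src, , , drop = FALSE],
                        arr[, src, , drop = FALSE],
                        arr[, , src, drop = FALSE])
    out <- out + kernel[[j]] * slice_src
  }
  out
}

gaussian_filter_3d <- function(arr, sigma) {
  k <- gaussian_kernel_1d(sigma)
  arr |>
    convolve_axis(k, 1L) |>
    convolve_axis(k, 2L) |>
    convolve_axis(k, 3L)
}

# 6-neighbour discrete Laplacian with replicated borders.
laplacian_3d <- function(arr) {
  d <- dim(arr)
  shift <- function(axis, by) {
    src <- pmin(pmax(seq_len(d[[axis]]) + by, 1L), d[[axis]])
    switch(axis,
           arr[src, , , drop = FALSE],
           arr[, src, , drop = FALSE],
           arr[, , src, drop = FALSE])
  }
  shift(1, 1) + shift(1, -1) + shift(2, 1) + shift(2, -1) +
    shift(3, 1) + shift(3, -1) - 6 * arr
}

# Negated Laplacian-of-Gaussian: bright blobs become maxima.
log_filter_3d <- function(arr, sigma) {
  -laplacian_3d(gaussian_filter_3d(arr, sigma))
}

# 26-connectivity connected components of a logical 3D array.
# Returns an integer label array (0 = background).
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nz <- d[[1]]; ny <- d[[2]]; nx <- d[[3]]
  lin <- which(mask)
  if (!length(lin)) return(labels)
  # precompute neighbour offsets in linear index space with coordinate checks
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  current <- 0L
  for (seed in lin) {
    if (labels[[seed]] != 0L) next
    current <- current + 1L
    queue <- seed
    labels[[seed]] <- current
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      z <- v0 %% nz
      y <- (v0 %/% nz) %% ny
      x <- v0 %/% (nz * ny)
      nbz <- z + offs$dz
      nby <- y + offs$dy
      nbx <- x + offs$dx
      ok <- nbz >= 0 & nbz < nz & nby >= 0 & nby < ny & nbx >= 0 & nbx < nx
      nb <- 1L + nbz[ok] + nz * (nby[ok] + ny * nbx[ok])
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- current
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

otsu_threshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  mat <- matrix((values - rng[[1]]) / diff(rng), nrow = 1L)
  thr <- EBImage::otsu(mat, range = c(0, 1), levels = levels)
  thr * diff(rng) + rng[[1]]
}
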