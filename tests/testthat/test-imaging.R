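test_that("a planted Gaussian spot is found at its true center", {
  g <- gen_image_stack(shape = c(16, 32, 32), n_spots = 1, spot_sigma = 1.5,
                       peak_intensity = 100, noise_sd = 0, seed = 61)
  sp <- detect_spots(g$stack, log_sigma = 1, thr = 3)
  expect_equal(nrow(sp), 1L)
  err <- sqrt((sp$z - g$truth$z)^2 + (sp$y - g$truth$y)^2 + (sp$x - g$truth$x)^2)
  expect_lt(err, 0.5)
  expect_gt(sp$total_intensity, 0)
})

test_that("a flat image yields no spots", {
  blank <- array(0, c(8, 16, 16))
  expect_equal(nrow(detect_spots(blank)), 0L)
  flat <- array(5, c(8, 16, 16))
  expect_equal(nrow(detect_spots(flat)), 0L)
})

test_that("4D stacks are thresholded per frame with a common thr", {
  g1 <- gen_image_stack(shape = c(8, 32, 32), n_spots = 2, spot_sigma = 1.5,
                        peak_intensity = 100, noise_sd = 0, seed = 62)
  g2 <- gen_image_stack(shape = c(8, 32, 32), n_spots = 3, spot_sigma = 1.5,
                        peak_intensity = 100, noise_sd = 0, seed = 63)
  movie <- array(0, c(2, 8, 32, 32))
  movie[1, , , ] <- g1$stack
  movie[2, , , ] <- g2$stack
  sp <- detect_spots(movie, log_sigma = 1, thr = 3)
  expect_equal(sum(sp$frame == 1), 2L)
  expect_equal(sum(sp$frame == 2), 3L)
})

test_that("nuclei segmentation covers bright discs and spares background", {
  img <- array(1, c(4, 128, 128))
  img[, 20:50, 20:50] <- 100
  img[, 70:110, 60:100] <- 120
  mask <- segment_nuclei(img, gauss_sigma = 1)
  truth <- array(FALSE, dim(img))
  truth[, 20:50, 20:50] <- TRUE
  truth[, 70:110, 60:100] <- TRUE
  expect_gte(mean(mask[truth]), 0.95)
  expect_lte(mean(mask[!truth]), 0.05)

  # global intensity scaling leaves the mask essentially unchanged
  mask2 <- segment_nuclei(img * 10, gauss_sigma = 1)
  expect_gt(mean(mask == mask2), 0.98)

  expect_warning(m0 <- segment_nuclei(array(0, c(2, 16, 16)), gauss_sigma = 1),
                 "constant")
  expect_false(any(m0))
})

test_that("spots are filtered by nuclei membership", {
  mask <- array(FALSE, c(4, 16, 16))
  mask[2, 5:10, 5:10] <- TRUE
  spots <- tibble::tibble(frame = 1L, z = c(2, 2), y = c(7, 14), x = c(7, 14),
                          total_intensity = c(10, 20), n_voxels = c(3L, 3L))
  kept <- filter_spots_in_nuclei(spots, mask)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$y, 7)
  full <- array(TRUE, c(4, 16, 16))
  expect_equal(nrow(filter_spots_in_nuclei(spots, full)), 2L)
})

test_that("mutual nearest pairing respects anisotropy and the 1-um cutoff", {
  A <- tibble::tibble(z = 0, y = 0, x = 0)
  near <- mutual_nearest_pairs(A, tibble::tibble(z = 0, y = 0, x = 0.5),
                               voxel_xy = 1, voxel_z = 1)
  expect_equal(near$distance, 0.5)
  far <- mutual_nearest_pairs(A, tibble::tibble(z = 0, y = 0, x = 1.2),
                              voxel_xy = 1, voxel_z = 1)
  expect_equal(nrow(far), 0L)

  # z contribution scales with voxel_z
  a <- tibble::tibble(z = 0, y = 0, x = 0)
  b <- tibble::tibble(z = 2, y = 0, x = 0)
  d1 <- mutual_nearest_pairs(a, b, voxel_xy = 0.1, voxel_z = 0.15,
                             max_dist = Inf)$distance
  d2 <- mutual_nearest_pairs(a, b, voxel_xy = 0.1, voxel_z = 0.30,
                             max_dist = Inf)$distance
  expect_equal(d2 / d1, 2)

  expect_equal(nrow(mutual_nearest_pairs(A[0, ], A)), 0L)
})

test_that("mutual nearest pairing equals the brute-force oracle", {
  set.seed(64)
  for (i in 1:25) {
    nA <- sample(1:12, 1)
    nB <- sample(1:12, 1)
    A <- tibble::tibble(z = runif(nA, 0, 10), y = runif(nA, 0, 50),
                        x = runif(nA, 0, 50))
    B <- tibble::tibble(z = runif(nB, 0, 10), y = runif(nB, 0, 50),
                        x = runif(nB, 0, 50))
    got <- mutual_nearest_pairs(A, B, voxel_xy = 0.046, voxel_z = 0.3,
                                max_dist = 1.0)
    want <- oracle_mnn(A, B, 0.046, 0.3, 1.0)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_true(all(got$distance <= 1.0))
    # symmetry up to orientation
    rev <- mutual_nearest_pairs(B, A, voxel_xy = 0.046, voxel_z = 0.3,
                                max_dist = 1.0)
    expect_equal(nrow(rev), nrow(got))
  }
})

test_that("transcription-site intensities are background-normalized", {
  spots <- tibble::tibble(total_intensity = c(100, 50))
  rois <- list(rep(8, 10), rep(9, 10), rep(10, 10), rep(11, 10),
               rep(12, 10), rep(13, 10))
  out <- spot_intensity_normalized(spots, rois)
  expect_equal(attr(out, "background"), mean(8:13))
  expect_equal(out$intensity_norm, c(100, 50) / mean(8:13))
  # ratio is invariant under a global intensity scaling
  out2 <- spot_intensity_normalized(
    dplyr::mutate(spots, total_intensity = total_intensity * 2),
    lapply(rois, function(r) r * 2))
  expect_equal(out2$intensity_norm, out$intensity_norm)
  expect_error(spot_intensity_normalized(spots, list()),
               class = "mitobook_input_error")
})

test_that("mitosis-persistent spots are removed from the next cycle", {
  spots <- tibble::tibble(frame = c(5L, 10L, 10L),
                          z = c(2, 2, 6), y = c(3, 3, 12), x = c(3, 3, 12),
                          total_intensity = 1, n_voxels = 1L)
  out <- filter_de_novo(spots, mitosis_frames = c(4, 6), radius = 0.5,
                        voxel_xy = 0.1, voxel_z = 0.1)
  # the post-mitotic spot at the mitotic position is removed; the distant one kept
  expect_equal(nrow(out), 2L)
  expect_true(all(out$y != 3 | out$frame == 5L))

  no_mito <- filter_de_novo(spots, mitosis_frames = c(100, 110), radius = 0.5)
  expect_identical(no_mito, spots)

  # random placements equal an explicit distance check
  set.seed(65)
  for (i in 1:10) {
    sp <- tibble::tibble(frame = sample(c(1L, 5L), 30, TRUE),
                         z = runif(30, 0, 10), y = runif(30, 0, 30),
                         x = runif(30, 0, 30))
    got <- filter_de_novo(sp, mitosis_frames = c(1, 1), radius = 1,
                          voxel_xy = 0.2, voxel_z = 0.2)
    mito <- sp[sp$frame == 1L, ]
    keep <- vapply(seq_len(nrow(sp)), function(j) {
      if (sp$frame[[j]] <= 1L) return(TRUE)
      dmin <- min(sqrt(((sp$x[[j]] - mito$x) * 0.2)^2 +
                       ((sp$y[[j]] - mito$y) * 0.2)^2 +
                       ((sp$z[[j]] - mito$z) * 0.2)^2))
      dmin > 1
    }, logical(1))
    expect_equal(as.data.frame(got), as.data.frame(sp[keep, ]),
                 ignore_attr = TRUE)
  }
})
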