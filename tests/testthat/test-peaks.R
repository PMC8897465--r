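test_that("RPM rescaling is a pure scaling of bin values", {
  trk <- coverage_track("chr2L", c(2, 4))
  expect_equal(rescale_rpm(trk, 2e6)$score, c(1, 2))
  expect_equal(rescale_rpm(trk, 1e6)$score, trk$score)
  # linearity
  set.seed(3)
  v <- runif(50, 0, 10)
  k <- 3.7
  expect_equal(rescale_rpm(coverage_track("c", k * v), 5e5)$score,
               k * rescale_rpm(coverage_track("c", v), 5e5)$score)
  expect_error(rescale_rpm(trk, 0), class = "mitobook_input_error")
})

test_that("input subtraction floors at zero unless told otherwise", {
  chip <- coverage_track("chr2L", c(5, 1))
  input <- coverage_track("chr2L", c(2, 3))
  expect_equal(subtract_input(chip, input)$score, c(3, 0))
  expect_equal(subtract_input(chip, input, floor_at_zero = FALSE)$score, c(3, -2))
  zero <- coverage_track("chr2L", c(0, 0))
  expect_equal(subtract_input(chip, zero)$score, chip$score)
  expect_error(subtract_input(chip, coverage_track("chr2L", c(1, 1), bin_size = 25)),
               class = "mitobook_input_error")
  expect_error(subtract_input(chip, coverage_track("chrX", c(1, 1))),
               class = "mitobook_input_error")
})

test_that("replicate averaging is the per-bin arithmetic mean", {
  a <- coverage_track("chr2L", c(0, 2))
  b <- coverage_track("chr2L", c(2, 0))
  expect_equal(mean_replicates(list(a, b))$score, c(1, 1))
  expect_equal(mean_replicates(list(a))$score, a$score)
  expect_equal(mean_replicates(list(a, a, a))$score, a$score)
  expect_error(mean_replicates(list(a, coverage_track("chr2L", 1:3))),
               class = "mitobook_input_error")
})

test_that("peak calling reproduces worked run/merge/filter examples", {
  trk <- coverage_track("chr2L", c(10, 120, 130, 5, 5, 140, 150, 150, 10, 10))
  one <- call_peaks(trk, threshold = 100, min_run = 50, max_gap = 200)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(50L, 400L))
  expect_equal(one$n_enriched_bins, 5L)

  two <- call_peaks(trk, threshold = 100, min_run = 50, max_gap = 50)
  expect_equal(two$start, c(50L, 250L))
  expect_equal(two$end, c(150L, 400L))

  none <- call_peaks(trk, threshold = 1000, min_run = 50, max_gap = 200)
  expect_equal(nrow(none), 0L)
})

test_that("peak calling is bit-identical to the brute-force oracle", {
  set.seed(11)
  for (i in 1:150) {
    trk <- random_track(n_bins = 200)
    thr <- sample(c(60, 100, 150), 1)
    mr <- sample(c(0, 50, 100, 150), 1)
    mg <- sample(c(0, 50, 100, 200, 400), 1)
    got <- call_peaks(trk, thr, mr, mg)
    want <- oracle_call_peaks(trk, thr, mr, mg)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$end, as.integer(want$end))
      expect_equal(got$max_value, want$max_value)
      expect_identical(got$n_enriched_bins, as.integer(want$n_enriched_bins))
    }
  }
})

test_that("with zero gap peaks are exactly the enriched runs of min length", {
  set.seed(12)
  for (i in 1:25) {
    trk <- random_track(n_bins = 150)
    got <- call_peaks(trk, 100, 100, 0)
    runs <- oracle_call_peaks(trk, 100, 100, 0)
    expect_equal(got$start, as.integer(runs$start))
    # every reported region is wall-to-wall enriched
    for (j in seq_len(nrow(got))) {
      bins <- trk[trk$chrom == got$chrom[[j]] &
                  trk$start >= got$start[[j]] & trk$end <= got$end[[j]], ]
      expect_true(all(bins$score >= 100))
    }
  }
})

test_that("raising the threshold never increases total peak base pairs", {
  set.seed(13)
  for (i in 1:20) {
    trk <- random_track(n_bins = 200)
    bp <- vapply(c(60, 90, 120, 160), function(thr) {
      p <- call_peaks(trk, thr, 50, 200)
      sum(p$end - p$start)
    }, numeric(1))
    expect_true(all(diff(bp) <= 0))
  }
})

test_that("retention classification follows the 1-bp overlap rule", {
  inter <- tibble::tibble(chrom = "chr2L", start = 0L, end = 100L)
  touching <- classify_peaks(inter, tibble::tibble(chrom = "chr2L", start = 99L, end = 150L))
  expect_equal(touching$class[touching$origin == "interphase"], "mitotically_retained")
  expect_false("mitosis_only" %in% touching$class)

  disjoint <- classify_peaks(inter, tibble::tibble(chrom = "chr2L", start = 100L, end = 150L))
  expect_equal(disjoint$class[disjoint$origin == "interphase"], "interphase_only")
  expect_equal(disjoint$class[disjoint$origin == "mitotic"], "mitosis_only")
})

test_that("classification counts match the O(n^2) oracle and are symmetric", {
  set.seed(14)
  for (i in 1:20) {
    mk <- function(n) {
      s <- as.integer(sample(0:5000, n))
      tibble::tibble(chrom = sample(c("cA", "cB"), n, replace = TRUE),
                     start = s, end = s + as.integer(sample(50:400, n, TRUE)))
    }
    A <- mk(sample(3:15, 1))
    B <- mk(sample(3:15, 1))
    got <- classify_peaks(A, B)
    want <- oracle_classify(A, B)
    tab <- table(got$class[got$origin == "interphase"])
    expect_equal(sum(got$origin == "interphase" &
                     got$class == "mitotically_retained"), want$retained)
    expect_equal(sum(got$class == "interphase_only"), want$interphase_only)
    expect_equal(sum(got$class == "mitosis_only"), want$mitosis_only)
    # symmetry: swapping arguments flags the same mitotic peaks as overlapping
    swapped <- classify_peaks(B, A)
    expect_equal(sum(swapped$origin == "interphase" &
                     swapped$class == "mitotically_retained"),
                 sum(got$origin == "mitotic" &
                     got$class == "mitotically_retained"))
  }
})

test_that("motif counting matches the sliding-window oracle", {
  g <- c(s = "GAGAGAG")
  pk <- tibble::tibble(chrom = "s", start = 0L, end = 7L)
  expect_equal(count_motif(pk, g)$motif_count, 2L)
  expect_equal(count_motif(pk, c(s = "CTCTCTT"))$motif_count, 1L)
  expect_equal(count_motif(pk, c(s = "TTTTTTT"))$motif_count, 0L)

  set.seed(15)
  for (i in 1:40) {
    k <- sample(3:8, 1)
    parts <- c(paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
               strrep("GA", k),
               paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
    seqstr <- paste(parts, collapse = "")
    genome <- setNames(list(seqstr), "chrZ")
    genome <- unlist(genome)
    pk <- tibble::tibble(chrom = "chrZ", start = 0L, end = nchar(seqstr))
    for (both in c(TRUE, FALSE)) {
      for (ovl in c(TRUE, FALSE)) {
        got <- count_motif(pk, genome, both_strands = both,
                           overlapping = ovl)$motif_count
        want <- oracle_count_motif(seqstr, "GAGAG", both, ovl)
        expect_equal(got, as.integer(want))
      }
    }
  }
  expect_error(count_motif(tibble::tibble(chrom = "s", start = 0L, end = 99L), g),
               class = "mitobook_input_error")
})

test_that("promoter/enhancer annotation applies the stated precedence", {
  tss <- tibble::tibble(chrom = "c", start = 150L, end = 151L)
  enh <- tibble::tibble(chrom = "c", start = 0L, end = 60L)
  pk <- tibble::tibble(chrom = "c", start = 0L, end = 100L)
  ann <- annotate_peaks(pk, tss, enh, tss_flank = 100)
  expect_equal(ann$annotation, "promoter")  # window [50,250) overlaps, wins over enhancer

  far_tss <- tibble::tibble(chrom = "c", start = 5000L, end = 5001L)
  expect_equal(annotate_peaks(pk, far_tss, enh)$annotation, "enhancer")
  expect_equal(annotate_peaks(pk, far_tss, tibble::tibble(
    chrom = "c", start = 900L, end = 950L))$annotation, "other")

  # random instances vs direct interval arithmetic
  set.seed(16)
  for (i in 1:20) {
    pk <- tibble::tibble(chrom = "c", start = as.integer(sample(0:2000, 8)))
    pk$end <- pk$start + as.integer(sample(50:300, 8, TRUE))
    tss <- tibble::tibble(chrom = "c", start = as.integer(sample(0:2000, 3)))
    tss$end <- tss$start + 1L
    enh <- tibble::tibble(chrom = "c", start = as.integer(sample(0:2000, 3)))
    enh$end <- enh$start + as.integer(sample(50:200, 3, TRUE))
    got <- annotate_peaks(pk, tss, enh, tss_flank = 100)$annotation
    want <- vapply(seq_len(nrow(pk)), function(j) {
      prom <- any(pk$start[[j]] < tss$start + 100 & tss$start - 100 < pk$end[[j]])
      enhh <- any(pk$start[[j]] < enh$end & enh$start < pk$end[[j]])
      if (prom) "promoter" else if (enhh) "enhancer" else "other"
    }, character(1))
    expect_equal(got, want)
    props <- attr(annotate_peaks(pk, tss, enh), "proportions")
    expect_equal(sum(props$proportion), 1)
  }
})

test_that("metagene matrices center on peaks with zero fill", {
  trk <- coverage_track("c", rep(7, 100))
  pk <- tibble::tibble(chrom = "c", start = 2000L, end = 2400L)
  mg <- metagene_matrix(trk, pk, flank = 1000)
  expect_equal(ncol(mg$matrix), 2 * 1000 / 50)
  expect_equal(unname(mg$profile$mean_score), rep(7, 40))
  expect_equal(mg$matrix[1, ], mg$profile$mean_score)

  # out-of-bounds positions are zero-filled
  edge <- tibble::tibble(chrom = "c", start = 0L, end = 100L)
  mge <- metagene_matrix(trk, edge, flank = 1000)
  expect_true(any(mge$matrix[1, ] == 0))
  expect_true(any(mge$matrix[1, ] == 7))
})
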