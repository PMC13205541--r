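test_that("binarize_roi applies a strict threshold inside the ROI only", {
  mono <- matrix(c(0.2, 0.6), 4, 4)
  roi <- matrix(1L, 4, 4)

  # threshold 0 keeps every ROI pixel with positive intensity
  expect_identical(binarize_roi(mono, roi, 0), roi)
  # threshold 1 is strict, so nothing survives
  expect_equal(sum(binarize_roi(mono, roi, 1)), 0L)
  # enumerated 4x4 two-level case
  out <- binarize_roi(mono, roi, 0.5)
  expect_identical(out, matrix(as.integer(mono == 0.6), 4, 4))
  # pixels outside the ROI are always 0
  roi2 <- matrix(0L, 4, 4); roi2[1, ] <- 1L
  expect_equal(sum(binarize_roi(mono, roi2, 0)[-1, ]), 0L)

  expect_error(binarize_roi(mono, roi, 1.2), class = "fviq_config_error")
  expect_error(binarize_roi(mono, matrix(1L, 3, 4), 0.5),
               class = "fviq_validation_error")
})

test_that("binarize_roi matches a per-pixel brute-force loop", {
  set.seed(21)
  for (rep in 1:6) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    mono <- matrix(runif(h * w), h, w)
    roi <- matrix(rbinom(h * w, 1, 0.6), h, w)
    thr <- runif(1)
    expected <- matrix(0L, h, w)
    for (r in seq_len(h)) for (c in seq_len(w))
      if (roi[r, c] == 1L && mono[r, c] > thr) expected[r, c] <- 1L
    expect_identical(binarize_roi(mono, roi, thr), expected)
  }
})

test_that("raising the threshold never adds pixels", {
  set.seed(22)
  mono <- matrix(runif(30 * 30), 30, 30)
  roi <- matrix(rbinom(900, 1, 0.7), 30, 30)
  thresholds <- sort(runif(6))
  counts <- vapply(thresholds, function(t) sum(binarize_roi(mono, roi, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("auto_threshold maximises between-class variance and rejects flat ROIs", {
  # clear bimodal ROI: threshold strictly between the modes
  mono <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  roi <- matrix(1L, 10, 10)
  t <- auto_threshold(mono, roi)
  expect_gt(t, 0.1)
  expect_lt(t, 0.9)

  # Otsu objective: no 256-bin candidate scores higher than the returned cut
  set.seed(23)
  vals <- c(rnorm(300, 0.3, 0.05), rnorm(200, 0.75, 0.04))
  vals <- pmin(pmax(vals, 0), 1)
  mono2 <- matrix(vals, 25, 20)
  t2 <- auto_threshold(mono2, matrix(1L, 25, 20))
  bcv_at <- brute_bcv(vals, t2)
  bcv_all <- vapply((0:255) / 256, function(cand) brute_bcv(vals, cand),
                    numeric(1))
  expect_gte(bcv_at, max(bcv_all) - 1e-12)

  # constant ROI: explicit degenerate error, never a silent threshold
  expect_error(auto_threshold(matrix(0.4, 5, 5), matrix(1L, 5, 5)),
               class = "fviq_degenerate_roi", regexp = "override")
})

test_that("segment_view resolves thresholds, unions ROIs and clips to the face", {
  fx <- two_patch_image()
  spec <- filter_spec(combiner = "blue", clahe_enabled = FALSE)

  # no patch ROIs: empty mask, empty count list
  empty_ann <- view_annotation("frontal", fx$ann$face, list())
  res0 <- segment_view(fx$img, empty_ann, spec)
  expect_equal(sum(res0$mask), 0L)
  expect_length(res0$per_roi_pixel_counts, 0L)

  # two disjoint 50-px rectangles segment to counts [50, 50], union 100
  res <- segment_view(fx$img, fx$ann, spec, global_threshold = 0.5)
  expect_equal(res$per_roi_pixel_counts, c(50L, 50L))
  expect_equal(sum(res$mask), 100L)
  expect_equal(res$thresholds_used, c(0.5, 0.5))

  # per-ROI override beats the global threshold
  patches <- fx$ann$patches
  patches[[1]] <- polygon_roi(patches[[1]]$vertices, kind = "patch",
                              threshold = 0.3)
  ann_ovr <- view_annotation("frontal", fx$ann$face, patches)
  res_ovr <- segment_view(fx$img, ann_ovr, spec, global_threshold = 0.7)
  expect_equal(res_ovr$thresholds_used, c(0.3, 0.7))

  # view labels must match
  img_left <- woods_image(fx$img$pixels, view = "left")
  expect_error(segment_view(img_left, fx$ann, spec),
               class = "fviq_validation_error")

  # the vitiligo mask is a subset of the face mask
  spec_default <- synthetic_patient_spec(seed = 31, views = "frontal",
                                         image_size = c(128L, 128L),
                                         coverage_per_view = 0.2)
  pat <- generate_patient(spec_default)
  seg <- segment_view(pat$images$frontal, pat$annotations$frontal)
  expect_true(all(seg$mask <= seg$face_mask))
})

test_that("overlapping ROIs report per-ROI counts but a union mask", {
  fx <- two_patch_image(rect1 = c(5, 5, 15, 10), rect2 = c(10, 5, 20, 10))
  spec <- filter_spec(combiner = "blue", clahe_enabled = FALSE)
  res <- segment_view(fx$img, fx$ann, spec, global_threshold = 0.5)
  expect_gte(sum(res$per_roi_pixel_counts), sum(res$mask))
  expect_equal(sum(res$mask), 15L * 5L)  # union of the two rectangles
})

test_that("dice_coefficient follows its closed form", {
  a <- matrix(0L, 10, 10); a[1:10, 1:10 <= 5] <- 1L  # 50 px
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0L, 10, 10); b[, 6:10] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = 100, |B| = 100, overlap 50
  a2 <- matrix(0L, 20, 10); a2[1:10, ] <- 1L
  b2 <- matrix(0L, 20, 10); b2[6:15, ] <- 1L
  expect_equal(dice_coefficient(a2, b2), 0.5)
  # both empty: defined as 1
  expect_equal(dice_coefficient(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(0L, 9, 10)),
               class = "fviq_validation_error")
})
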