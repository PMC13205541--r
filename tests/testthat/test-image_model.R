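test_that("woods_image validates dimensions, range and view label", {
  px <- array(0, dim = c(4, 4, 3))
  img <- woods_image(px, view = "frontal")
  expect_equal(img$width, 4L)
  expect_equal(img$height, 4L)
  expect_error(woods_image(px, view = "sideways"),
               class = "fviq_validation_error")
  px_bad <- px; px_bad[1, 1, 1] <- 300
  expect_error(woods_image(px_bad, view = "frontal"),
               class = "fviq_validation_error")
  expect_error(woods_image(array(0, dim = c(4, 4, 2)), view = "frontal"),
               class = "fviq_validation_error")
})

test_that("read_woods_image decodes PNG, replicates grayscale, rescales 16-bit", {
  # 4x4 all-black PNG
  p1 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0, dim = c(4, 4, 3)), p1)
  img <- read_woods_image(p1, view = "frontal")
  expect_equal(dim(img$pixels), c(4L, 4L, 3L))
  expect_true(all(img$pixels == 0L))

  # grayscale PNG replicated to three identical channels
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 0.5, 1, 0.25), 2, 2), p2)
  img2 <- read_woods_image(p2, view = "left")
  expect_identical(img2$pixels[, , 1], img2$pixels[, , 2])
  expect_identical(img2$pixels[, , 1], img2$pixels[, , 3])

  # 2x2 16-bit TIFF with full-range values: endpoints map to endpoints
  p3 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(c(0, 1, 1, 0), 2, 2), p3, bits.per.sample = 16L)
  img3 <- read_woods_image(p3, view = "right")
  expect_equal(sort(unique(as.vector(img3$pixels))), c(0L, 255L))

  expect_error(read_woods_image("no/such/file.png", view = "frontal"),
               class = "fviq_input_error")
  expect_no_error(read_woods_image(p1, view = "frontal", patient_id = "x",
                                   timepoint = "t"))
})

test_that("annotation files parse, validate and round-trip bit-exactly", {
  path <- write_minimal_annotation()
  ann <- read_annotation(path)
  expect_s3_class(ann, "view_annotation")
  expect_length(ann$patches, 1L)
  expect_equal(ann$face$vertices, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))

  # out-of-range override rejected
  bad <- write_minimal_annotation(patch_threshold = 1.5)
  expect_error(read_annotation(bad), class = "fviq_validation_error")

  # per-patch overrides preserved
  ok <- write_minimal_annotation(patch_threshold = 0.4)
  expect_equal(read_annotation(ok)$patches[[1]]$threshold, 0.4)

  # missing face outline
  nf <- withr::local_tempfile(fileext = ".json")
  writeLines('{"view": "frontal", "patches": []}', nf)
  expect_error(read_annotation(nf), class = "fviq_validation_error")

  # self-intersecting patch named by index
  si <- withr::local_tempfile(fileext = ".json")
  doc <- list(view = "frontal",
              face = list(vertices = list(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
              patches = list(list(vertices = list(c(0, 0), c(4, 4), c(4, 0), c(0, 4)))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), si)
  expect_error(read_annotation(si), regexp = "patch ROI 1",
               class = "fviq_validation_error")

  # write/read round-trip preserves vertices and overrides exactly
  ann2 <- view_annotation(
    "left",
    polygon_roi(rbind(c(0.1, 0.2), c(33.25, 1 / 3), c(17.5, 29.9)),
                kind = "face_outline"),
    list(polygon_roi(rbind(c(5.5, 6.25), c(9.125, 6.5), c(7, 11.75)),
                     kind = "patch", threshold = 0.123456789))
  )
  rt <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann2, rt)
  ann3 <- read_annotation(rt)
  expect_identical(ann3$face$vertices, ann2$face$vertices)
  expect_identical(ann3$patches[[1]]$vertices, ann2$patches[[1]]$vertices)
  expect_identical(ann3$patches[[1]]$threshold, ann2$patches[[1]]$threshold)
})

test_that("polygon_roi rejects degenerate and out-of-contract inputs", {
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1)), kind = "patch"),
               class = "fviq_validation_error")
  expect_error(polygon_roi(rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))),
               class = "fviq_validation_error")  # bow-tie
  expect_error(polygon_roi(rbind(c(0, 0), c(10, 0), c(5, 5)),
                           kind = "face_outline", threshold = 0.5),
               class = "fviq_validation_error")
})

test_that("rasterisation uses the centre-in even-odd rule", {
  # axis-aligned square with integer corners covers exactly w*h pixels
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  m <- rasterize_polygon(sq, 20, 20)
  expect_equal(sum(m), 100L)
  expect_true(all(m[1:10, 1:10] == 1L))

  # polygon entirely outside the image rasterises to an empty mask
  far <- rbind(c(100, 100), c(110, 100), c(105, 110))
  expect_equal(sum(rasterize_polygon(far, 20, 20)), 0L)

  # determinism
  tri <- rbind(c(1.5, 2.5), c(17.1, 3.3), c(9.9, 18.2))
  expect_identical(rasterize_polygon(tri, 20, 20),
                   rasterize_polygon(tri, 20, 20))

  # degenerate polygon: warning + empty mask, not an error
  expect_warning(z <- rasterize_polygon(rbind(c(1, 1), c(5, 5), c(3, 3)), 10, 10),
                 "degenerate")
  expect_equal(sum(z), 0L)
})

test_that("rasterisation matches the brute-force even-odd oracle", {
  set.seed(42)
  for (rep in 1:8) {
    w <- sample(16:64, 1); h <- sample(16:64, 1)
    poly <- random_simple_polygon(sample(5:12, 1),
                                  cx = w / 2, cy = h / 2,
                                  r_min = 2, r_max = min(w, h) * 0.6)
    expect_identical(rasterize_polygon(poly, w, h),
                     brute_rasterize(poly, w, h),
                     info = sprintf("replicate %d (%dx%d)", rep, w, h))
  }

  # rectangles with non-integer corners also agree with the oracle
  rect <- rbind(c(2.3, 1.7), c(13.8, 1.7), c(13.8, 9.2), c(2.3, 9.2))
  expect_identical(rasterize_polygon(rect, 16, 12), brute_rasterize(rect, 16, 12))
})

test_that("synthetic writer output reads back as three distinct views", {
  spec <- synthetic_patient_spec(seed = 5, image_size = c(96L, 96L),
                                 coverage_per_view = 0.1,
                                 n_patches_per_view = 2L)
  pat <- generate_patient(spec)
  dir <- withr::local_tempdir()
  write_patient(pat, dir)
  imgs <- lapply(c("frontal", "left", "right"), function(v)
    read_woods_image(file.path(dir, paste0(v, ".png")), view = v))
  expect_setequal(vapply(imgs, `[[`, character(1), "view"),
                  c("frontal", "left", "right"))
  # pixel-exact PNG round-trip
  expect_identical(imgs[[1]]$pixels, pat$images$frontal$pixels)
  # annotations round-trip
  ann <- read_annotation(file.path(dir, "frontal.json"))
  expect_identical(ann$face$vertices, pat$annotations$frontal$face$vertices)
})
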