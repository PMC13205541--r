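# Synthetic Wood's-light patients: dark bluish background skin with bright
# bluish-white depigmented blobs of known geometry, plus the rough polygonal
# ROIs an operator would draw around them. Every stage of the pipeline can
# be validated against the generator's ground-truth masks, since no clinical
# image set is publicly deposited.

#' Specification of a synthetic patient
#'
#' @param seed integer RNG seed; all outputs are bit-reproducible from it.
#' @param views subset of `c("frontal", "left", "right")`.
#' @param image_size `(width, height)` in pixels.
#' @param coverage_per_view target vitiligo fraction of the face per view,
#'   in `[0, 0.8]`.
#' @param n_patches_per_view number of distinct patches per view.
#' @param patch_contrast intensity gap between patch and background skin in
#'   `[0, 1]` (fraction of the 8-bit range, added to the green and blue
#'   channels).
#' @param noise_sd Gaussian pixel noise standard deviation on the `[0, 1]`
#'   intensity scale.
#' @param illumination_gradient add a linear left-to-right illumination ramp
#'   (x0.75 to x1.25)?
#' @return An object of class `synthetic_patient_spec`.
#' @export
synthetic_patient_spec <- function(seed,
                                   views = c("frontal", "left", "right"),
                                   image_size = c(256L, 256L),
                                   coverage_per_view = 0.15,
                                   n_patches_per_view = 3L,
                                   patch_contrast = 0.5,
                                   noise_sd = 0.02,
                                   illumination_gradient = FALSE) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("'seed' must be a single integer")
  views <- unique(as.character(views))
  if (!length(views) || !all(views %in% VIEW_LABELS))
    stop_validation("'views' must be a non-empty subset of frontal/left/right")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 32L))
    stop_validation("'image_size' must be (width, height), each >= 32 px")
  if (!is.numeric(coverage_per_view) || coverage_per_view < 0 ||
      coverage_per_view > 0.8)
    stop_validation("'coverage_per_view' must lie in [0, 0.8]")
  if (n_patches_per_view < 1L)
    stop_validation("'n_patches_per_view' must be >= 1")
  if (patch_contrast < 0 || patch_contrast > 1)
    stop_validation("'patch_contrast' must lie in [0, 1]")
  if (noise_sd < 0)
    stop_validation("'noise_sd' must be non-negative")
  structure(list(seed = as.integer(seed), views = views,
                 image_size = image_size,
                 coverage_per_view = coverage_per_view,
                 n_patches_per_view = as.integer(n_patches_per_view),
                 patch_contrast = patch_contrast, noise_sd = noise_sd,
                 illumination_gradient = isTRUE(illumination_gradient)),
            class = "synthetic_patient_spec")
}

# Face outline polygon: a filled ellipse for the frontal view, half-ellipses
# for the profile views.
face_polygon <- function(view, w, h) {
  cx <- w / 2; cy <- h / 2
  if (view == "frontal") {
    a <- 0.36 * w; b <- 0.44 * h
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  } else {
    a <- 0.30 * w; b <- 0.44 * h
    th <- if (view == "left") seq(pi / 2, 3 * pi / 2, length.out = 33L)
          else seq(-pi / 2, pi / 2, length.out = 33L)
  }
  cbind(cx + a * cos(th), cy + b * sin(th))
}

scale_polygon <- function(verts, factor) {
  ctr <- colMeans(verts)
  sweep(sweep(verts, 2, ctr), 2, c(factor, factor), `*`) |>
    sweep(2, ctr, `+`)
}

# Paint the union of discs into a 0/1 matrix (pixel-centre inclusion).
paint_discs <- function(centers, radii, w, h) {
  mask <- matrix(0L, nrow = h, ncol = w)
  for (k in seq_along(radii)) {
    r <- radii[k]
    if (r <= 0) next
    cx <- centers[k, 1]; cy <- centers[k, 2]
    cols <- max(1L, floor(cx - r + 0.5)):min(w, ceiling(cx + r + 0.5))
    rows <- max(1L, floor(cy - r + 0.5)):min(h, ceiling(cy + r + 0.5))
    if (!length(cols) || !length(rows)) next
    dx2 <- (cols - 0.5 - cx)^2
    dy2 <- (rows - 0.5 - cy)^2
    mask[rows, cols] <- mask[rows, cols] | outer(dy2, dx2, `+`) <= r^2
  }
  storage.mode(mask) <- "integer"
  mask
}

# Monotone bisection for the disc scale that realises a target pixel count.
bisect_coverage <- function(f, target, lo, hi, tol = 0.03, iter = 42L) {
  if (f(hi) < target * (1 - tol))
    stop_generation("requested coverage is unreachable for this face geometry")
  best_s <- hi; best_err <- abs(f(hi) / target - 1)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    err <- abs(v / target - 1)
    if (err < best_err) { best_err <- err; best_s <- mid }
    if (err <= tol) return(mid)
    if (v < target) lo <- mid else hi <- mid
  }
  if (best_err > 0.10)
    stop_generation(sprintf(
      "coverage search did not converge (best relative error %.3f)", best_err))
  best_s
}

# Generate the geometry and rasters for one view. All random draws happen
# up front so the deterministic coverage search never perturbs the RNG
# stream.
generate_view <- function(spec, view, subseed) {
  set.seed(subseed)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  fpoly <- face_polygon(view, w, h)
  face_mask <- rasterize_polygon(fpoly, w, h)
  face_px <- sum(face_mask)

  geometry <- list(face_poly = fpoly, centers = NULL, radii = NULL,
                   patch_of_disc = integer(0))
  truth <- matrix(0L, nrow = h, ncol = w)
  patches <- list()
  realized <- 0

  if (spec$coverage_per_view > 0) {
    core <- rasterize_polygon(scale_polygon(fpoly, 0.7), w, h)
    core_idx <- which(core == 1L)
    if (length(core_idx) < spec$n_patches_per_view)
      stop_generation("face too small for the requested number of patches")
    seeds_idx <- sample(core_idx, spec$n_patches_per_view)
    pcy <- (seeds_idx - 1L) %% h + 0.5
    pcx <- (seeds_idx - 1L) %/% h + 0.5

    # equivalent-circle radius of one patch, used to scale disc offsets
    off_scale <- sqrt(spec$coverage_per_view * face_px /
                        (pi * spec$n_patches_per_view))
    centers <- NULL; rel_r <- NULL; patch_of_disc <- integer(0)
    for (p in seq_len(spec$n_patches_per_view)) {
      nd <- sample(3:6, 1L)
      off <- matrix(stats::rnorm(2L * nd, sd = 0.6 * off_scale), ncol = 2L)
      centers <- rbind(centers, cbind(pcx[p] + off[, 1], pcy[p] + off[, 2]))
      rel_r <- c(rel_r, stats::runif(nd, 0.6, 1))
      patch_of_disc <- c(patch_of_disc, rep.int(p, nd))
    }

    target_px <- spec$coverage_per_view * face_px
    cov_px <- function(s) sum(paint_discs(centers, rel_r * s, w, h) * face_mask)
    s <- bisect_coverage(cov_px, target_px, lo = 0.1,
                         hi = 6 * off_scale + 10)
    radii <- rel_r * s
    truth <- paint_discs(centers, radii, w, h) * face_mask
    realized <- sum(truth) / face_px
    geometry$centers <- centers
    geometry$radii <- radii
    geometry$patch_of_disc <- patch_of_disc
    patches <- roi_polygons(centers, radii, patch_of_disc)
  }

  ann <- view_annotation(
    view = view,
    face = polygon_roi(fpoly, kind = "face_outline"),
    patches = patches
  )
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  list(face_mask = face_mask, truth = truth, annotation = ann,
       realized = realized, geometry = geometry, noise_seed = noise_seed)
}

# Rough operator-style ROI per patch: convex hull of points sampled on each
# disc's circle at radius + 5 px margin, so the ROI deliberately over-covers
# the patch and leaves the pixel-level work to segmentation.
roi_polygons <- function(centers, radii, patch_of_disc, margin = 5) {
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  lapply(sort(unique(patch_of_disc)), function(p) {
    k <- which(patch_of_disc == p)
    pts <- do.call(rbind, lapply(k, function(i) {
      r <- radii[i] + margin
      cbind(centers[i, 1] + r * cos(ang), centers[i, 2] + r * sin(ang))
    }))
    hull <- grDevices::chull(pts)
    polygon_roi(pts[hull, , drop = FALSE], kind = "patch")
  })
}

# Render a Wood's-light-like RGB image from a face mask and truth mask.
render_view_image <- function(spec, view, face_mask, truth, noise_seed) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  bg  <- c(8, 8, 20)    # non-face background
  skin <- c(20, 20, 60) # dark, low-fluorescence facial skin
  gain <- spec$patch_contrast * 255
  px <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], nrow = h, ncol = w)
    plane[face_mask == 1L] <- skin[ch]
    if (ch >= 2L) plane[truth == 1L] <- skin[ch] + gain  # G and B fluoresce
    px[, , ch] <- plane
  }
  if (spec$illumination_gradient) {
    ramp <- matrix(seq(0.75, 1.25, length.out = w), nrow = h, ncol = w,
                   byrow = TRUE)
    for (ch in 1:3) px[, , ch] <- px[, , ch] * ramp
  }
  set.seed(noise_seed)
  px <- px + stats::rnorm(length(px), sd = spec$noise_sd * 255)
  px <- round(pmin(pmax(px, 0), 255))
  woods_image(px, view = view,
              patient_id = sprintf("synthetic-%d", spec$seed))
}

#' Generate a synthetic patient
#'
#' Builds, for each requested view, a Wood's-light-like image, its
#' ground-truth patch mask, and the annotation an operator would supply
#' (face-outline polygon plus one rough convex ROI per patch). Patch
#' geometry is a union of random overlapping discs seeded inside the face;
#' disc radii are scaled by a deterministic search so the realised coverage
#' matches `coverage_per_view` to within a few percent. Identical specs
#' produce bit-identical output.
#'
#' @param spec a [synthetic_patient_spec()].
#' @return An object of class `synthetic_patient` with named-by-view lists
#'   `images`, `truth_masks`, `face_masks`, `annotations`, and the numeric
#'   vector `realized_coverage`.
#' @export
generate_patient <- function(spec) {
  stopifnot(inherits(spec, "synthetic_patient_spec"))
  set.seed(spec$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(spec$views))
  views <- spec$views
  out <- list(images = list(), truth_masks = list(), face_masks = list(),
              annotations = list(), realized_coverage = numeric(0),
              geometry = list(), noise_seeds = integer(0), spec = spec)
  for (i in seq_along(views)) {
    v <- views[i]
    g <- generate_view(spec, v, subseeds[i])
    img <- render_view_image(spec, v, g$face_mask, g$truth, g$noise_seed)
    img$timepoint <- "baseline"
    out$images[[v]] <- img
    out$truth_masks[[v]] <- g$truth
    out$face_masks[[v]] <- g$face_mask
    out$annotations[[v]] <- g$annotation
    out$realized_coverage[v] <- g$realized
    out$geometry[[v]] <- g$geometry
    out$noise_seeds[v] <- g$noise_seed
  }
  class(out) <- "synthetic_patient"
  out
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> seed %d, %d view(s), %dx%d px\n",
              x$spec$seed, length(x$images),
              x$spec$image_size[1], x$spec$image_size[2]))
  for (v in names(x$images))
    cat(sprintf("  %s: coverage %.4f\n", v, x$realized_coverage[[v]]))
  invisible(x)
}

#' Generate a before/after pair with known repigmentation
#'
#' The follow-up patient reuses the baseline geometry with every disc
#' shrunk in place (centres fixed, radii scaled by a deterministic search)
#' so the follow-up truth coverage is
#' `(1 - repigmentation_fraction) * baseline coverage`, emulating
#' repigmentation that recedes patches from their edges. Annotations are
#' identical at both timepoints; the follow-up image carries fresh pixel
#' noise, as a new photograph would.
#'
#' @param spec a [synthetic_patient_spec()].
#' @param repigmentation_fraction fraction of baseline patch area cleared at
#'   follow-up, in `[0, 1]`.
#' @return A list with elements `before` and `after`, both
#'   `synthetic_patient` objects.
#' @export
generate_longitudinal_pair <- function(spec, repigmentation_fraction) {
  if (!is.numeric(repigmentation_fraction) ||
      length(repigmentation_fraction) != 1L ||
      is.na(repigmentation_fraction) ||
      repigmentation_fraction < 0 || repigmentation_fraction > 1)
    stop_validation("'repigmentation_fraction' must lie in [0, 1]")
  before <- generate_patient(spec)
  after <- before
  w <- spec$image_size[1]; h <- spec$image_size[2]
  set.seed(spec$seed + 1L)
  follow_noise <- sample.int(.Machine$integer.max - 1L, length(spec$views))
  for (i in seq_along(spec$views)) {
    v <- spec$views[i]
    geom <- before$geometry[[v]]
    face_mask <- before$face_masks[[v]]
    face_px <- sum(face_mask)
    keep <- 1 - repigmentation_fraction
    if (length(geom$radii) == 0L || keep == 1) {
      truth <- before$truth_masks[[v]]
    } else if (keep == 0) {
      truth <- matrix(0L, nrow = h, ncol = w)
    } else {
      target_px <- keep * sum(before$truth_masks[[v]])
      cov_px <- function(t)
        sum(paint_discs(geom$centers, geom$radii * t, w, h) * face_mask)
      t <- bisect_coverage(cov_px, target_px, lo = 0, hi = 1, tol = 0.03)
      truth <- paint_discs(geom$centers, geom$radii * t, w, h) * face_mask
    }
    img <- render_view_image(spec, v, face_mask, truth, follow_noise[i])
    img$timepoint <- "followup"
    after$images[[v]] <- img
    after$truth_masks[[v]] <- truth
    after$realized_coverage[v] <- sum(truth) / face_px
    after$noise_seeds[v] <- follow_noise[i]
  }
  list(before = before, after = after)
}

#' Write a synthetic patient to disk
#'
#' Writes, per view, the image (`<view>.png`), the ground-truth mask
#' (`<view>_truth.png`, 0/255), and the annotation (`<view>.json`), plus a
#' `manifest.json` with the spec and realised coverages.
#'
#' @param patient a `synthetic_patient`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(patient$images)) {
    png::writePNG(patient$images[[v]]$pixels / 255,
                  file.path(dir, paste0(v, ".png")))
    png::writePNG(patient$truth_masks[[v]] * 1.0,
                  file.path(dir, paste0(v, "_truth.png")))
    write_annotation(patient$annotations[[v]],
                     file.path(dir, paste0(v, ".json")))
  }
  manifest <- list(
    patient_id = patient$images[[1]]$patient_id,
    timepoint = patient$images[[1]]$timepoint,
    seed = patient$spec$seed,
    views = names(patient$images),
    image_size = patient$spec$image_size,
    requested_coverage = patient$spec$coverage_per_view,
    realized_coverage = as.list(patient$realized_coverage)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
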