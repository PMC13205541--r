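VIEW_LABELS <- c("frontal", "left", "right")

#' Wood's-light face image
#'
#' Container for one facial view photographed under Wood's-light (long-wave
#' UV-A) illumination, stored as an 8-bit RGB raster together with its view
#' label and patient/timepoint metadata. Depigmented skin fluoresces under
#' this illumination, so vitiligo patches appear as bright bluish-white
#' regions on dark, low-fluorescence background skin.
#'
#' Pixels are stored as an `height x width x 3` integer array with channel
#' values in `[0, 255]`. The coordinate convention throughout the package is:
#' origin at the top-left corner, `x` increasing rightwards (columns), `y`
#' increasing downwards (rows), 0-based pixel indices, so pixel `(x, y)`
#' occupies the unit square with centre `(x + 0.5, y + 0.5)`.
#'
#' @param pixels numeric array `h x w x 3`, values in `[0, 255]`.
#' @param view one of `"frontal"`, `"left"`, `"right"`.
#' @param patient_id opaque patient identifier.
#' @param timepoint ordinal label such as `"baseline"` or `"followup"`.
#' @return An object of class `woods_image` with fields `pixels`, `width`,
#'   `height`, `view`, `patient_id`, `timepoint`.
#' @export
woods_image <- function(pixels, view, patient_id = "", timepoint = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("'pixels' must be an h x w x 3 array of RGB values")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_validation("image must have width >= 1 and height >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_validation("channel values must lie in [0, 255]")
  if (length(view) != 1L || !view %in% VIEW_LABELS)
    stop_validation(sprintf("'view' must be one of: %s",
                            paste(VIEW_LABELS, collapse = ", ")))
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         width = dim(pixels)[2], height = dim(pixels)[1],
         view = view, patient_id = patient_id, timepoint = timepoint),
    class = "woods_image"
  )
}

#' @export
print.woods_image <- function(x, ...) {
  cat(sprintf("<woods_image> %dx%d px, view '%s', patient '%s', timepoint '%s'\n",
              x$width, x$height, x$view, x$patient_id, x$timepoint))
  invisible(x)
}

#' Read a Wood's-light photograph
#'
#' Reads a PNG, JPEG or TIFF raster into a [woods_image()]. Grayscale inputs
#' are replicated to three identical channels; an alpha channel, if present,
#' is dropped; 16-bit samples are rescaled to 8-bit by integer division
#' (`v %/% 257`), mapping the full 16-bit range onto `[0, 255]` with the
#' endpoints preserved. View, patient and timepoint are explicit metadata
#' supplied by the caller (or a sidecar annotation), never guessed from the
#' file name or image content.
#'
#' @param path path to a PNG/JPEG/TIFF file, 8- or 16-bit, 1-4 channels.
#' @inheritParams woods_image
#' @return A [woods_image()].
#' @export
read_woods_image <- function(path, view, patient_id = "", timepoint = "") {
  if (!file.exists(path))
    stop_input(sprintf("image file does not exist: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = round(png::readPNG(path) * 255),
      jpg  = ,
      jpeg = round(jpeg::readJPEG(path) * 255),
      tif  = ,
      tiff = read_tiff_8bit(path),
      stop_input(sprintf("unsupported image extension '%s' for '%s'", ext, path))
    ),
    error = function(e) {
      if (inherits(e, "fviq_error")) stop(e)
      stop_input(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)))
    }
  )
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]       # drop alpha
  if (dim(raw)[3] == 2L) raw <- raw[, , 1L, drop = FALSE]        # gray+alpha
  if (dim(raw)[3] == 1L) raw <- array(raw, c(dim(raw)[1:2], 3L)) # replicate gray
  woods_image(raw, view = view, patient_id = patient_id, timepoint = timepoint)
}

# TIFF decode with explicit bit-depth handling: 16-bit samples are reduced to
# 8-bit by integer division by 257 so that 0 -> 0 and 65535 -> 255.
read_tiff_8bit <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  img <- unclass(img)
  attributes(img) <- list(dim = dim(img))
  if (bits > 8L) img <- img %/% 257L
  img
}

#' Polygonal region of interest
#'
#' An operator-drawn polygon in continuous pixel coordinates: either the
#' face outline or a rough polygon enclosing one suspected vitiligo patch.
#' Patch ROIs may carry a per-ROI binarisation threshold override in
#' `[0, 1]`, taking precedence over any global threshold.
#'
#' @param vertices numeric `n x 2` matrix (or coercible) of `(x, y)` points,
#'   `n >= 3`; the polygon is closed implicitly and must be simple
#'   (non-self-intersecting).
#' @param kind `"patch"` or `"face_outline"`.
#' @param threshold optional override in `[0, 1]`; only allowed for patches.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, kind = c("patch", "face_outline"),
                        threshold = NULL) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop_validation("polygon needs a numeric n x 2 vertex matrix with n >= 3")
  if (anyNA(vertices)) stop_validation("polygon vertices must not contain NA")
  if (!is_simple_polygon(vertices))
    stop_validation("polygon is self-intersecting")
  if (!is.null(threshold)) {
    if (kind != "patch")
      stop_validation("threshold overrides are only allowed on patch ROIs")
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1)
      stop_validation("threshold override must be a single number in [0, 1]")
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, kind = kind, threshold = threshold),
            class = "polygon_roi")
}

# Orientation of the triple (p, q, r): sign of the z-component of
# (q - p) x (r - p).
.orient <- function(px, py, qx, qy, rx, ry) {
  sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
}

.on_segment <- function(px, py, qx, qy, rx, ry) {
  # r collinear with pq assumed; is r within the bounding box of pq?
  rx >= min(px, qx) && rx <= max(px, qx) && ry >= min(py, qy) && ry <= max(py, qy)
}

.segments_intersect <- function(a, b, c, d) {
  o1 <- .orient(a[1], a[2], b[1], b[2], c[1], c[2])
  o2 <- .orient(a[1], a[2], b[1], b[2], d[1], d[2])
  o3 <- .orient(c[1], c[2], d[1], d[2], a[1], a[2])
  o4 <- .orient(c[1], c[2], d[1], d[2], b[1], b[2])
  if (o1 != o2 && o3 != o4) return(TRUE)
  if (o1 == 0 && .on_segment(a[1], a[2], b[1], b[2], c[1], c[2])) return(TRUE)
  if (o2 == 0 && .on_segment(a[1], a[2], b[1], b[2], d[1], d[2])) return(TRUE)
  if (o3 == 0 && .on_segment(c[1], c[2], d[1], d[2], a[1], a[2])) return(TRUE)
  if (o4 == 0 && .on_segment(c[1], c[2], d[1], d[2], b[1], b[2])) return(TRUE)
  FALSE
}

# A closed polygon is simple iff no two non-adjacent edges intersect.
is_simple_polygon <- function(vertices) {
  n <- nrow(vertices)
  vc <- rbind(vertices, vertices[1L, , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_intersect(vc[i, ], vc[i + 1L, ], vc[j, ], vc[j + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Per-view annotation: face outline plus patch ROIs
#'
#' @param view view label the annotation belongs to.
#' @param face a [polygon_roi()] of kind `face_outline`.
#' @param patches list of [polygon_roi()] of kind `patch` (possibly empty).
#' @return An object of class `view_annotation`.
#' @export
view_annotation <- function(view, face, patches = list()) {
  if (length(view) != 1L || !view %in% VIEW_LABELS)
    stop_validation(sprintf("'view' must be one of: %s",
                            paste(VIEW_LABELS, collapse = ", ")))
  if (!inherits(face, "polygon_roi") || face$kind != "face_outline")
    stop_validation("annotation must contain exactly one face_outline polygon")
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!inherits(p, "polygon_roi") || p$kind != "patch")
      stop_validation(sprintf("patch ROI %d is not a polygon_roi of kind 'patch'", i))
    if (!bbox_intersects(p$vertices, face$vertices))
      stop_validation(sprintf(
        "patch ROI %d lies entirely outside the face outline's bounding box", i))
  }
  structure(list(view = view, face = face, patches = patches),
            class = "view_annotation")
}

bbox_intersects <- function(a, b) {
  !(max(a[, 1]) < min(b[, 1]) || min(a[, 1]) > max(b[, 1]) ||
    max(a[, 2]) < min(b[, 2]) || min(a[, 2]) > max(b[, 2]))
}

#' @export
print.view_annotation <- function(x, ...) {
  cat(sprintf("<view_annotation> view '%s', %d patch ROI(s)\n",
              x$view, length(x$patches)))
  invisible(x)
}

#' Read / write a view annotation
#'
#' One JSON document per view:
#' `{"view": ..., "face": {"vertices": [[x,y],...]},`
#' `"patches": [{"vertices": [[x,y],...], "threshold": <optional>}]}`.
#' Vertices round-trip at full double precision, so reading a written
#' annotation reproduces the vertex coordinates bit-exactly.
#'
#' @param path path to the JSON annotation file.
#' @return `read_annotation()` returns a [view_annotation()];
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    stop_input(sprintf("annotation file does not exist: '%s'", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_input(sprintf("cannot parse annotation '%s': %s",
                                       path, conditionMessage(e))))
  if (is.null(doc$face) || is.null(doc$face$vertices))
    stop_validation(sprintf("annotation '%s' is missing the face outline", path))
  face <- tryCatch(
    polygon_roi(json_vertices(doc$face$vertices), kind = "face_outline"),
    error = function(e) stop_validation(
      sprintf("face outline: %s", conditionMessage(e))))
  patches <- lapply(seq_along(doc$patches), function(i) {
    p <- doc$patches[[i]]
    tryCatch(
      polygon_roi(json_vertices(p$vertices), kind = "patch",
                  threshold = if (!is.null(p$threshold)) as.numeric(p$threshold)),
      error = function(e) stop_validation(
        sprintf("patch ROI %d: %s", i, conditionMessage(e))))
  })
  view_annotation(view = as.character(doc$view), face = face, patches = patches)
}

json_vertices <- function(v) {
  do.call(rbind, lapply(v, function(pt) as.numeric(unlist(pt))))
}

#' @rdname read_annotation
#' @param ann a [view_annotation()].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "view_annotation"))
  doc <- list(
    view = ann$view,
    face = list(vertices = ann$face$vertices),
    patches = lapply(ann$patches, function(p) {
      out <- list(vertices = p$vertices)
      if (!is.null(p$threshold)) out$threshold <- p$threshold
      out
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' Rasterise a polygon to a binary mask
#'
#' A pixel belongs to the mask iff its centre `(x + 0.5, y + 0.5)` lies
#' inside the closed polygon under the even-odd rule. Parts of the polygon
#' outside the image are clipped. A degenerate (zero-area) polygon yields an
#' empty mask with a warning rather than an error.
#'
#' @param poly a [polygon_roi()] or an `n x 2` vertex matrix.
#' @param width,height output raster dimensions in pixels.
#' @return Integer `height x width` matrix of 0/1.
#' @export
rasterize_polygon <- function(poly, width, height) {
  if (inherits(poly, "polygon_roi")) poly <- poly$vertices
  poly <- as.matrix(poly)
  if (width < 1L || height < 1L)
    stop_validation("raster dimensions must be >= 1")
  mask <- matrix(0L, nrow = height, ncol = width)
  if (polygon_area(poly) == 0) {
    warning("degenerate zero-area polygon rasterised to an empty mask")
    return(mask)
  }
  cx <- seq_len(width) - 0.5   # pixel-centre x per column
  cy <- seq_len(height) - 0.5  # pixel-centre y per row
  n <- nrow(poly)
  vx <- poly[, 1]; vy <- poly[, 2]
  nxt <- c(2:n, 1L)
  parity <- matrix(0L, nrow = height, ncol = width)
  for (e in seq_len(n)) {
    y1 <- vy[e]; y2 <- vy[nxt[e]]
    if (y1 == y2) next
    x1 <- vx[e]; x2 <- vx[nxt[e]]
    rows <- which((y1 > cy) != (y2 > cy))
    if (!length(rows)) next
    xint <- x1 + (cy[rows] - y1) * (x2 - x1) / (y2 - y1)
    parity[rows, ] <- parity[rows, ] + outer(xint, cx, `>`)
  }
  mask[parity %% 2L == 1L] <- 1L
  mask
}
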