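# Step 2: binarise the filtered image inside each operator-drawn ROI and
# assemble the per-view 0-1 vitiligo map (0 = healthy skin, 1 = patch).

#' Binarise a monochrome image inside an ROI
#'
#' A pixel is set iff it lies in the ROI and its filtered intensity is
#' strictly greater than the threshold, so a threshold of 1 always yields an
#' empty mask and a threshold of 0 keeps every ROI pixel with non-zero
#' intensity.
#'
#' @param mono numeric matrix in `[0, 1]` (a filtered image).
#' @param roi_mask 0/1 matrix of the same dimensions.
#' @param threshold number in `[0, 1]`.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
binarize_roi <- function(mono, roi_mask, threshold) {
  if (!identical(dim(mono), dim(roi_mask)))
    stop_validation("'mono' and 'roi_mask' dimensions differ")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop_config("threshold must be a single number in [0, 1]")
  out <- matrix(0L, nrow = nrow(mono), ncol = ncol(mono))
  out[roi_mask == 1L & mono > threshold] <- 1L
  out
}

#' Automatic threshold for one ROI (Otsu)
#'
#' Computes the Otsu threshold over the filtered intensities inside the ROI
#' only, on a 256-bin histogram; it maximises the between-class variance of
#' the two-class split. Stands in for the interactive threshold choice an
#' operator would make, giving a reproducible default that per-ROI overrides
#' or a global threshold can replace. A constant ROI has no two classes to
#' separate and raises a degenerate-ROI error asking for a manual override.
#'
#' @param mono numeric matrix in `[0, 1]`.
#' @param roi_mask 0/1 matrix of the same dimensions with at least one pixel
#'   set.
#' @return A threshold in `[0, 1]`.
#' @export
auto_threshold <- function(mono, roi_mask) {
  if (!identical(dim(mono), dim(roi_mask)))
    stop_validation("'mono' and 'roi_mask' dimensions differ")
  vals <- mono[roi_mask == 1L]
  if (length(vals) < 2L || diff(range(vals)) == 0)
    stop_degenerate_roi(paste0(
      "ROI intensities are constant; no automatic threshold exists - ",
      "supply a manual threshold override for this ROI"))
  as.numeric(EBImage::otsu(matrix(vals, ncol = 1L), range = c(0, 1),
                           levels = 256L))
}

#' Segment one view
#'
#' Runs the full per-view detection: filter the image ([apply_filter()]),
#' rasterise the face outline and every patch ROI, binarise each ROI at its
#' effective threshold, and return the union of the per-ROI masks clipped to
#' the face. The effective threshold for an ROI is resolved by precedence:
#' the ROI's own override if present, else `global_threshold` if supplied,
#' else the automatic Otsu threshold of that ROI.
#'
#' @param img a [woods_image()].
#' @param ann a [view_annotation()] whose view label matches `img`.
#' @param spec a [filter_spec()].
#' @param global_threshold optional number in `[0, 1]` applied to every ROI
#'   without an override.
#' @return An object of class `segmentation_result` with fields `mask`
#'   (0/1 matrix, the per-view vitiligo map), `face_mask`,
#'   `per_roi_pixel_counts`, `thresholds_used`, `filter_spec`, `view`.
#' @export
segment_view <- function(img, ann, spec = filter_spec(),
                         global_threshold = NULL) {
  stopifnot(inherits(img, "woods_image"), inherits(ann, "view_annotation"))
  if (img$view != ann$view)
    stop_validation(sprintf("image view '%s' does not match annotation view '%s'",
                            img$view, ann$view))
  if (!is.null(global_threshold) &&
      (!is.numeric(global_threshold) || length(global_threshold) != 1L ||
       global_threshold < 0 || global_threshold > 1))
    stop_config("global threshold must be a single number in [0, 1]")

  mono <- apply_filter(img, spec)
  face_mask <- rasterize_polygon(ann$face, img$width, img$height)
  mask <- matrix(0L, nrow = img$height, ncol = img$width)
  n_roi <- length(ann$patches)
  counts <- integer(n_roi)
  thresholds <- numeric(n_roi)
  for (i in seq_len(n_roi)) {
    roi <- rasterize_polygon(ann$patches[[i]], img$width, img$height)
    thr <- ann$patches[[i]]$threshold
    if (is.null(thr)) thr <- global_threshold
    if (is.null(thr)) thr <- auto_threshold(mono, roi)
    bin <- binarize_roi(mono, roi, thr)
    bin <- bin * face_mask  # patch pixels outside the face outline don't count
    counts[i] <- sum(bin)
    thresholds[i] <- thr
    mask[bin == 1L] <- 1L
  }
  structure(
    list(mask = mask, face_mask = face_mask,
         per_roi_pixel_counts = counts, thresholds_used = thresholds,
         filter_spec = spec, view = ann$view),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> view '%s': %d vitiligo px / %d face px (%d ROI)\n",
              x$view, sum(x$mask), sum(x$face_mask),
              length(x$per_roi_pixel_counts)))
  if (length(x$thresholds_used))
    cat("  thresholds:", paste(sprintf("%.4f", x$thresholds_used),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks, the standard overlap
#' score of a segmentation against ground truth; defined as 1 when both
#' masks are empty.
#'
#' @param mask_a,mask_b 0/1 matrices of identical dimensions.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_validation("mask dimensions differ")
  na <- sum(mask_a == 1L); nb <- sum(mask_b == 1L)
  if (na + nb == 0L) return(1)
  2 * sum(mask_a == 1L & mask_b == 1L) / (na + nb)
}
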