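# Steps 3-4: normalise detected patch area by face area per view and
# average the per-view ratios into the Face Vitiligo Index (FVI), a single
# number per patient in [0, 1]: 0 when no patches are detectable, 1 when the
# face is fully depigmented. Normalising by face area makes the index
# comparable across images of different size, resolution and face framing.

#' Per-view vitiligo/face pixel ratio
#'
#' Counts vitiligo pixels inside the face and total face pixels for one
#' view. The ratio `p_v / p_f` is the view's contribution to the FVI.
#'
#' @param mask 0/1 vitiligo map (e.g. `segment_view(...)$mask`), or a
#'   `segmentation_result` (its stored face mask is then used).
#' @param face_mask 0/1 face-region matrix of the same dimensions with at
#'   least one pixel set; ignored when `mask` is a `segmentation_result`.
#' @param view optional view label carried into the result.
#' @return An object of class `view_index_result` with fields `view`,
#'   `vitiligo_pixels`, `face_pixels`, `ratio`.
#' @export
view_index <- function(mask, face_mask = NULL, view = NA_character_) {
  if (inherits(mask, "segmentation_result")) {
    if (is.na(view)) view <- mask$view
    face_mask <- mask$face_mask
    mask <- mask$mask
  }
  if (is.null(face_mask))
    stop_validation("'face_mask' is required when 'mask' is a plain matrix")
  if (!identical(dim(mask), dim(face_mask)))
    stop_validation("mask and face mask dimensions differ")
  pf <- sum(face_mask == 1L)
  if (pf == 0L)
    stop_validation("face mask is empty; the vitiligo/face ratio is undefined")
  pv <- sum(mask == 1L & face_mask == 1L)
  structure(list(view = view, vitiligo_pixels = pv, face_pixels = pf,
                 ratio = pv / pf),
            class = "view_index_result")
}

#' @export
print.view_index_result <- function(x, ...) {
  cat(sprintf("<view_index_result> view '%s': %d / %d px, ratio %.4f\n",
              x$view, x$vitiligo_pixels, x$face_pixels, x$ratio))
  invisible(x)
}

#' Face Vitiligo Index
#'
#' Averages the per-view vitiligo/face ratios into a single patient-level
#' index, `FVI = mean_i p_v,i / p_f,i` over the available views (the
#' canonical case uses the frontal, left and right views, divisor 3). When
#' fewer than three views are available the mean is taken over those
#' provided and `n_views` flags it; missing views are never imputed as zero,
#' which would understate disease.
#'
#' @param per_view a list of [view_index()] results (1-3 entries, distinct
#'   view labels), or a single result.
#' @return An object of class `fvi_result` with fields `per_view`,
#'   `fvi_fraction` (in `[0, 1]`), `fvi_percent` (`= 100 * fvi_fraction`),
#'   `n_views`.
#' @export
face_vitiligo_index <- function(per_view) {
  if (inherits(per_view, "view_index_result")) per_view <- list(per_view)
  if (!is.list(per_view) || length(per_view) == 0L)
    stop_validation("at least one per-view index is required")
  if (length(per_view) > 3L)
    stop_validation("at most three views (frontal, left, right) are supported")
  if (!all(vapply(per_view, inherits, logical(1), "view_index_result")))
    stop_validation("'per_view' must contain view_index results")
  labels <- vapply(per_view, function(v) as.character(v$view), character(1))
  known <- labels[!is.na(labels)]
  if (anyDuplicated(known))
    stop_validation("duplicate view labels in per-view indices")
  fraction <- mean(vapply(per_view, function(v) v$ratio, numeric(1)))
  structure(list(per_view = per_view, fvi_fraction = fraction,
                 fvi_percent = 100 * fraction, n_views = length(per_view)),
            class = "fvi_result")
}

#' @export
print.fvi_result <- function(x, ...) {
  cat(sprintf("<fvi_result> FVI = %.4f (%.2f%%) over %d view(s)\n",
              x$fvi_fraction, x$fvi_percent, x$n_views))
  if (x$n_views < 3L)
    cat("  note: fewer than three views; mean taken over available views\n")
  invisible(x)
}

#' Percent change between two assessments
#'
#' `100 * (before - after) / before`: positive values mean improvement
#' (repigmentation of an area index, or reduction of a questionnaire
#' score). The full-precision value is returned; reports round it to one
#' decimal via [round_pct()].
#'
#' @param before baseline value, strictly positive.
#' @param after follow-up value on the same scale, non-negative.
#' @return Signed percentage (unrounded).
#' @export
percent_change <- function(before, after) {
  if (!is.numeric(before) || length(before) != 1L || is.na(before) || before <= 0)
    stop_validation("'before' must be a single positive number")
  if (!is.numeric(after) || length(after) != 1L || is.na(after) || after < 0)
    stop_validation("'after' must be a single non-negative number")
  100 * (before - after) / before
}

#' Round a percentage for reporting
#' @param x percentage value(s).
#' @return `x` rounded to one decimal.
#' @export
round_pct <- function(x) round(x, 1)

#' F-VASI from fingertip units
#'
#' The Facial Vitiligo Area Scoring Index is estimated clinically by
#' counting imaginary thumbs ("fingertip units") laid side by side over the
#' depigmented area, each corresponding to 0.1% of body surface area.
#'
#' @param units non-negative fingertip-unit count (fractional counts
#'   allowed).
#' @return An object of class `fvasi_estimate` with fields
#'   `fingertip_units_depigmented` and `fvasi` (percent of body surface
#'   area, `= 0.1 * units`).
#' @export
fvasi_from_units <- function(units) {
  if (!is.numeric(units) || length(units) != 1L || is.na(units) || units < 0)
    stop_validation("fingertip-unit count must be a single non-negative number")
  structure(list(fingertip_units_depigmented = units, fvasi = 0.1 * units),
            class = "fvasi_estimate")
}

#' @export
print.fvasi_estimate <- function(x, ...) {
  cat(sprintf("<fvasi_estimate> %.3g fingertip units -> F-VASI %.3g%% BSA\n",
              x$fingertip_units_depigmented, x$fvasi))
  invisible(x)
}
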