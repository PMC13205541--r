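# Patient-level assessment containers and longitudinal change reports.
# Reports are self-contained: every derived number in them can be
# recomputed from the stored before/after values.

METRIC_FIELDS <- c("fvi_percent", "fvasi", "vdlqi", "vitiqol")

#' Patient assessment at one timepoint
#'
#' Bundles whatever metrics were acquired at one visit: the image-derived
#' FVI, the clinician-estimated F-VASI, and the two questionnaire totals.
#' At least one metric must be present.
#'
#' @param patient_id patient identifier.
#' @param timepoint ordinal label, e.g. `"baseline"`.
#' @param fvi an [face_vitiligo_index()] result, or a bare FVI value on the
#'   percent scale.
#' @param fvasi an [fvasi_from_units()] result, or a bare F-VASI value
#'   (percent of body surface area).
#' @param vdlqi vDLQI total in `[0, 42]`.
#' @param vitiqol VitiQoL total in `[0, 90]`.
#' @return An object of class `patient_assessment`.
#' @export
patient_assessment <- function(patient_id, timepoint, fvi = NULL,
                               fvasi = NULL, vdlqi = NULL, vitiqol = NULL) {
  fvi_percent <- if (inherits(fvi, "fvi_result")) fvi$fvi_percent
                 else if (!is.null(fvi)) as.numeric(fvi)
  fvasi_val <- if (inherits(fvasi, "fvasi_estimate")) fvasi$fvasi
               else if (!is.null(fvasi)) as.numeric(fvasi)
  metrics <- list(fvi_percent = fvi_percent, fvasi = fvasi_val,
                  vdlqi = if (!is.null(vdlqi)) as.numeric(vdlqi),
                  vitiqol = if (!is.null(vitiqol)) as.numeric(vitiqol))
  if (all(vapply(metrics, is.null, logical(1))))
    stop_validation("a patient assessment needs at least one metric")
  n_views <- if (inherits(fvi, "fvi_result")) fvi$n_views else NA_integer_
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 metrics = metrics, n_views = n_views,
                 fvi_detail = if (inherits(fvi, "fvi_result")) fvi),
            class = "patient_assessment")
}

#' @export
print.patient_assessment <- function(x, ...) {
  cat(sprintf("<patient_assessment> patient '%s', timepoint '%s'\n",
              x$patient_id, x$timepoint))
  for (m in METRIC_FIELDS)
    if (!is.null(x$metrics[[m]]))
      cat(sprintf("  %s: %.4g\n", m, x$metrics[[m]]))
  invisible(x)
}

#' Longitudinal change report for one patient
#'
#' Computes the percent change (positive = improvement) for every metric
#' present in both assessments; metrics present in only one are omitted
#' with a message. Percent changes are reported rounded to one decimal, the
#' unrounded values retained alongside.
#'
#' @param before,after [patient_assessment()] objects for the same patient
#'   at distinct timepoints.
#' @return An object of class `change_report`: a list with one entry per
#'   shared metric (`before`, `after`, `percent_change`,
#'   `percent_change_unrounded`) plus `patient_id` and the two timepoints.
#' @export
build_change_report <- function(before, after) {
  stopifnot(inherits(before, "patient_assessment"),
            inherits(after, "patient_assessment"))
  if (!identical(before$patient_id, after$patient_id))
    stop_validation(sprintf("patient ids differ: '%s' vs '%s'",
                            before$patient_id, after$patient_id))
  if (identical(before$timepoint, after$timepoint))
    stop_validation("before/after timepoints must be distinct")
  changes <- list()
  for (m in METRIC_FIELDS) {
    b <- before$metrics[[m]]; a <- after$metrics[[m]]
    if (is.null(b) || is.null(a)) {
      if (!is.null(b) || !is.null(a))
        message(sprintf("metric '%s' present at only one timepoint; omitted", m))
      next
    }
    pc <- percent_change(b, a)
    changes[[m]] <- list(before = b, after = a,
                         percent_change = round_pct(pc),
                         percent_change_unrounded = pc)
  }
  if (!length(changes))
    stop_validation("no metric is present in both assessments")
  structure(list(patient_id = before$patient_id,
                 timepoint_before = before$timepoint,
                 timepoint_after = after$timepoint,
                 changes = changes,
                 n_views = c(before = before$n_views, after = after$n_views)),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> patient '%s': %s -> %s\n",
              x$patient_id, x$timepoint_before, x$timepoint_after))
  for (m in names(x$changes)) {
    ch <- x$changes[[m]]
    cat(sprintf("  %-12s %8.4g -> %-8.4g  change %+.1f%%\n",
                m, ch$before, ch$after, ch$percent_change))
  }
  invisible(x)
}

#' @export
as.data.frame.change_report <- function(x, ...) {
  data.frame(
    patient_id = x$patient_id,
    metric = names(x$changes),
    before = vapply(x$changes, `[[`, numeric(1), "before"),
    after = vapply(x$changes, `[[`, numeric(1), "after"),
    percent_change = vapply(x$changes, `[[`, numeric(1), "percent_change"),
    row.names = NULL
  )
}

#' Cohort mean percent change per metric
#'
#' Unweighted arithmetic mean of the per-patient one-decimal percent
#' changes, itself reported to one decimal. Averaging the rounded
#' per-patient values matches how published per-patient percentages combine
#' into cohort figures.
#'
#' @param reports list of [build_change_report()] results (>= 1).
#' @return Named numeric vector, one mean percent change per metric present
#'   in at least one report.
#' @export
cohort_summary <- function(reports) {
  if (inherits(reports, "change_report")) reports <- list(reports)
  if (!is.list(reports) || !length(reports) ||
      !all(vapply(reports, inherits, logical(1), "change_report")))
    stop_validation("'reports' must be a non-empty list of change reports")
  out <- numeric(0)
  for (m in METRIC_FIELDS) {
    vals <- unlist(lapply(reports, function(r)
      if (!is.null(r$changes[[m]])) r$changes[[m]]$percent_change))
    if (length(vals)) out[m] <- round_pct(mean(vals))
  }
  out
}

#' Write a change report as JSON or CSV
#'
#' Both dialects carry identical values: the CSV is the flat
#' [as.data.frame.change_report()] table, the JSON the full nested report.
#'
#' @param report a [build_change_report()] result.
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_change_report <- function(report, path) {
  stopifnot(inherits(report, "change_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = I(17)), path)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    stop_config(sprintf("unsupported report extension '%s' (use .json or .csv)",
                        ext))
  }
  invisible(path)
}
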