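#' Published three-patient case series of ICI-induced facial vitiligo
#'
#' Baseline and follow-up values transcribed from a published case series of
#' three patients with immune-checkpoint-inhibitor-induced facial vitiligo
#' treated with topical ruxolitinib: FVI (percent scale), F-VASI (% body
#' surface area), and vDLQI / VitiQoL questionnaire totals. These are the
#' standard worked inputs for [build_change_report()] and
#' [cohort_summary()].
#'
#' @return A data.frame with columns `patient_id`, `metric` (one of
#'   `fvi_percent`, `fvasi`, `vdlqi`, `vitiqol`), `before`, `after`,
#'   `max_score` (instrument maximum, `NA` for area indices).
#' @export
read_case_series <- function() {
  path <- system.file("extdata", "case_series.csv", package = "fviq",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Change reports for the bundled case series
#'
#' Convenience wrapper: builds one [build_change_report()] per patient in
#' [read_case_series()].
#'
#' @return Named list of `change_report` objects, one per patient.
#' @export
case_series_reports <- function() {
  cs <- read_case_series()
  lapply(split(cs, cs$patient_id), function(d) {
    met <- function(tp) {
      get_m <- function(m, col) {
        v <- d[[col]][d$metric == m]
        if (length(v)) v else NULL
      }
      patient_assessment(
        patient_id = d$patient_id[1], timepoint = tp,
        fvi = get_m("fvi_percent", if (tp == "baseline") "before" else "after"),
        fvasi = get_m("fvasi", if (tp == "baseline") "before" else "after"),
        vdlqi = get_m("vdlqi", if (tp == "baseline") "before" else "after"),
        vitiqol = get_m("vitiqol", if (tp == "baseline") "before" else "after")
      )
    }
    build_change_report(met("baseline"), met("followup"))
  })
}
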