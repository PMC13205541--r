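# Quality-of-life instruments used alongside the imaging pipeline. The
# vitiligo-extended Dermatology Life Quality Index (vDLQI) adds four
# vitiligo-specific items to the ten DLQI items, all scored 0-3, total
# 0-42. VitiQoL is a vitiligo-specific instrument of fifteen 0-6 items,
# total 0-90. The item texts themselves are not shipped (the DLQI wording
# is copyrighted); responses are supplied as item-score vectors.

check_items <- function(items, n, max_score, label) {
  items <- as.numeric(items)
  if (length(items) != n)
    stop_validation(sprintf("%s requires exactly %d items, got %d",
                            label, n, length(items)))
  bad <- which(is.na(items) | items != floor(items) |
                 items < 0 | items > max_score)
  if (length(bad))
    stop_validation(sprintf("%s item %d is not an integer in [0, %d]",
                            label, bad[1], max_score))
  as.integer(items)
}

#' vDLQI response
#'
#' One patient-timepoint response to the vitiligo-extended DLQI: the ten
#' DLQI items followed by the four vitiligo add-on items (sun sensitivity,
#' worry about progression, sleep, low mood), each scored 0-3. "Not
#' relevant" answers are scored 0 per the instrument's standard rule.
#'
#' @param dlqi_items 10 integers in `[0, 3]`.
#' @param vitiligo_items 4 integers in `[0, 3]`.
#' @return An object of class `vdlqi_response`.
#' @export
vdlqi_response <- function(dlqi_items, vitiligo_items) {
  structure(
    list(dlqi_items = check_items(dlqi_items, 10L, 3L, "DLQI"),
         vitiligo_items = check_items(vitiligo_items, 4L, 3L, "vitiligo add-on")),
    class = "vdlqi_response"
  )
}

#' VitiQoL response
#'
#' @param items 15 integers in `[0, 6]`.
#' @return An object of class `vitiqol_response`.
#' @export
vitiqol_response <- function(items) {
  structure(list(items = check_items(items, 15L, 6L, "VitiQoL")),
            class = "vitiqol_response")
}

#' Score a vDLQI response
#'
#' Sum of all 14 items; range 0 (no impact on quality of life) to 42
#' (maximum impact).
#'
#' @param resp a [vdlqi_response()], or a plain numeric vector of 14 item
#'   scores (10 DLQI then 4 vitiligo items).
#' @return Integer total in `[0, 42]`.
#' @export
score_vdlqi <- function(resp) {
  if (is.numeric(resp) && length(resp) == 14L)
    resp <- vdlqi_response(resp[1:10], resp[11:14])
  if (!inherits(resp, "vdlqi_response"))
    stop_validation("'resp' must be a vdlqi_response or a 14-item vector")
  sum(resp$dlqi_items) + sum(resp$vitiligo_items)
}

#' Score a VitiQoL response
#'
#' Sum of all 15 items; range 0 to 90.
#'
#' @param resp a [vitiqol_response()] or a plain numeric vector of 15 item
#'   scores.
#' @return Integer total in `[0, 90]`.
#' @export
score_vitiqol <- function(resp) {
  if (is.numeric(resp) && length(resp) == 15L) resp <- vitiqol_response(resp)
  if (!inherits(resp, "vitiqol_response"))
    stop_validation("'resp' must be a vitiqol_response or a 15-item vector")
  sum(resp$items)
}

#' Percent change of a questionnaire score
#'
#' Delegates to [percent_change()] after range-checking both totals against
#' the instrument maximum; positive values mean score reduction
#' (improvement). A baseline of 0 leaves the relative change undefined -
#' report the absolute change instead.
#'
#' @param before,after integer totals in `[0, max_score]`.
#' @param max_score instrument maximum (42 for vDLQI, 90 for VitiQoL).
#' @return Signed percentage (unrounded).
#' @export
score_change <- function(before, after, max_score) {
  for (v in list(before = before, after = after)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > max_score)
      stop_validation(sprintf("scores must be single numbers in [0, %d]",
                              max_score))
  }
  if (before == 0)
    stop_fviq(paste0("baseline score is 0: relative change is undefined; ",
                     "report the absolute change instead"),
              c("fviq_undefined_change", "fviq_validation_error"))
  percent_change(before, after)
}
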