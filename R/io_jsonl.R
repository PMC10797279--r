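# Newline-delimited JSON serialization of patient timelines and the
# ground-truth sidecar. Numbers are written with 17 significant digits
# so a write/read cycle is an exact round trip.

timeline_to_plain <- function(tl) {
  list(
    patient_id = tl$patient_id,
    admissions = lapply(tl$admissions, function(r) {
      list(record_id = r$record_id, patient_id = r$patient_id,
           admit_date = r$admit_date, discharge_date = r$discharge_date,
           age = r$age, sex = r$sex, marital_status = r$marital_status,
           labs = as.list(r$labs),
           history_tokens = as.list(r$history_tokens),
           diagnosis_codes = as.list(r$diagnosis_codes),
           medication_codes = as.list(r$medication_codes))
    }),
    outcome_events = lapply(tl$outcome_events, function(e)
      list(date = e$date, kind = e$kind, code = e$code))
  )
}

plain_to_timeline <- function(p) {
  admissions <- lapply(p$admissions, function(r) {
    labs <- vapply(r$labs, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    discharge_record(
      record_id = r$record_id, patient_id = r$patient_id,
      admit_date = r$admit_date, discharge_date = r$discharge_date,
      age = r$age, sex = r$sex, marital_status = r$marital_status,
      labs = labs,
      history_tokens = unlist(r$history_tokens) %||% character(0),
      diagnosis_codes = unlist(r$diagnosis_codes) %||% character(0),
      medication_codes = unlist(r$medication_codes) %||% character(0))
  })
  structure(list(
    patient_id = p$patient_id,
    admissions = admissions,
    outcome_events = lapply(p$outcome_events, function(e)
      list(date = as.integer(e$date), kind = e$kind, code = e$code))
  ), class = "patient_timeline")
}

#' Write patient timelines to a JSONL file
#'
#' One `patient_timeline` per line. Missing lab values are written as
#' JSON `null`; doubles keep full precision so
#' `read_timelines(write_timelines(x))` reproduces `x` exactly.
#'
#' @param timelines list of `patient_timeline`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timelines <- function(timelines, path) {
  lines <- vapply(timelines, function(tl)
    as.character(jsonlite::toJSON(timeline_to_plain(tl), auto_unbox = TRUE,
                                  digits = I(17), na = "null", null = "null")),
    "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read patient timelines from a JSONL file
#'
#' @param path JSONL file written by [write_timelines()] (or conforming
#'   to the same schema).
#' @return list of `patient_timeline`. Malformed lines raise an error
#'   naming the line number.
#' @export
read_timelines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stopf("malformed JSONL at line %d: %s", i, conditionMessage(e)))
    out[[i]] <- tryCatch(
      plain_to_timeline(p),
      error = function(e) stopf("invalid timeline at line %d: %s", i, conditionMessage(e)))
  }
  out
}

#' Write the ground-truth sidecar
#'
#' Per-patient latent vectors and per-record event probabilities, kept
#' in a separate file so the modelling pipeline never sees them.
#'
#' @param timelines output of [generate_timelines()] (with the
#'   `ground_truth` attribute).
#' @param path output JSONL path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(timelines, path) {
  truth <- attr(timelines, "ground_truth")
  if (is.null(truth)) stopf("timelines carry no ground truth")
  lines <- vapply(truth, function(pt)
    as.character(jsonlite::toJSON(pt, auto_unbox = TRUE, digits = I(17),
                                  na = "null")), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
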