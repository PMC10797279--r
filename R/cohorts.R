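# Case-control cohort construction for 30/180/365-day post-discharge
# depression/anxiety prediction: outcome code sets, window labelling
# with a 183-day prior-event exclusion, 7-day repeat-record merging,
# and 1:k propensity-score matching on discharge time and
# days-to-event-or-window-end.

#' Depression/anxiety outcome code sets
#'
#' ICD-10 prefixes F31--F34, F39, F06.3 (depression) and F40--F43, F06.4
#' (anxiety); ATC prefixes N06A (antidepressants) and N05B
#' (anxiolytics). Matching is case-insensitive and dot-tolerant.
#'
#' @return object of class `outcome_code_sets`.
#' @export
outcome_code_sets <- function() {
  structure(list(
    depression_icd = c("F31", "F32", "F33", "F34", "F39", "F06.3"),
    anxiety_icd = c("F40", "F41", "F42", "F43", "F06.4"),
    antidepressant_atc = "N06A",
    anxiolytic_atc = "N05B"
  ), class = "outcome_code_sets")
}

norm_code <- function(x) gsub(".", "", toupper(x), fixed = TRUE)

#' Does a code match the depression/anxiety outcome definition?
#'
#' @param code character vector of codes.
#' @param kind `"diagnosis"` (checked against the ICD sets) or
#'   `"medication"` (ATC sets).
#' @param code_sets an [outcome_code_sets()].
#' @return logical vector.
#' @export
is_outcome_code <- function(code, kind, code_sets = outcome_code_sets()) {
  prefixes <- norm_code(switch(kind,
    diagnosis = c(code_sets$depression_icd, code_sets$anxiety_icd),
    medication = c(code_sets$antidepressant_atc, code_sets$anxiolytic_atc),
    stopf("unknown event kind '%s'", kind)))
  nc <- norm_code(code)
  vapply(nc, function(x) any(startsWith(x, prefixes)), NA, USE.NAMES = FALSE)
}

# outcome event days (relative day indices) of a timeline
outcome_event_days <- function(timeline, code_sets) {
  if (!length(timeline$outcome_events)) return(integer(0))
  hits <- vapply(timeline$outcome_events, function(e)
    is_outcome_code(e$code, e$kind, code_sets), NA)
  vapply(timeline$outcome_events[hits], function(e) as.integer(e$date), 0L)
}

#' Label one record against a prediction window
#'
#' A record is a *case* if a depression/anxiety outcome event falls in
#' the half-open window `(discharge, discharge + window_days]`;
#' *excluded* (reason `"prior_event"`) if any outcome event falls in
#' `[discharge - 183, discharge]` (short-term depression or anxiety in
#' the six months before discharge); otherwise *control*-eligible.
#' Non-matching event codes are ignored.
#'
#' @param timeline the `patient_timeline` owning the record.
#' @param record a `discharge_record` from that timeline.
#' @param window_days prediction window (30, 180 or 365).
#' @param code_sets an [outcome_code_sets()].
#' @return list with `status` in `c("case", "control", "excluded")`,
#'   `reason` (for exclusions), and `days_to_event` (cases: days from
#'   discharge to the first in-window event; controls: `window_days`).
#' @export
label_window <- function(timeline, record, window_days,
                         code_sets = outcome_code_sets()) {
  if (record$patient_id != timeline$patient_id)
    stopf("record %s does not belong to timeline %s",
          record$record_id, timeline$patient_id)
  days <- outcome_event_days(timeline, code_sets)
  dd <- record$discharge_date
  if (any(days >= dd - 183L & days <= dd))
    return(list(status = "excluded", reason = "prior_event",
                days_to_event = NA_integer_))
  in_window <- days[days > dd & days <= dd + window_days]
  if (length(in_window))
    return(list(status = "case", reason = NA_character_,
                days_to_event = as.integer(min(in_window) - dd)))
  list(status = "control", reason = NA_character_,
       days_to_event = as.integer(window_days))
}

#' Merge repeated records within one week
#'
#' Among any run of one patient's records whose discharge dates chain
#' within 7 days of each other (transitive closure), only the latest
#' record is kept.
#'
#' @param records one patient's `discharge_record` list, sorted by
#'   discharge date.
#' @return the reduced record list.
#' @export
merge_repeats <- function(records) {
  if (length(records) <= 1) return(records)
  dd <- vapply(records, function(r) r$discharge_date, 0L)
  if (is.unsorted(dd)) stopf("records must be sorted by discharge date")
  cluster <- cumsum(c(1L, as.integer(diff(dd) > 7L)))
  keep <- vapply(split(seq_along(records), cluster), max, 0L)
  records[sort(keep)]
}

#' Matching configuration
#'
#' @param control_ratio controls per case (default 3, giving the 1:3
#'   case-control ratio that emulates a 25\% depression rate).
#' @param caliper optional maximum |logit propensity| distance; `NULL`
#'   disables it.
#' @param seed integer seed (tie-breaks are deterministic anyway; the
#'   seed covers any stochastic fallback).
#' @return object of class `match_config`.
#' @export
match_config <- function(control_ratio = 3L, caliper = NULL, seed = 1L) {
  if (control_ratio < 1) stopf("control_ratio must be >= 1")
  structure(list(control_ratio = as.integer(control_ratio),
                 caliper = caliper, seed = as.integer(seed)),
            class = "match_config")
}

standardized_mean_diff <- function(x_case, x_ctrl) {
  sp <- sqrt((stats::var(x_case) + stats::var(x_ctrl)) / 2)
  if (!is.finite(sp) || sp == 0) return(0)
  abs(mean(x_case) - mean(x_ctrl)) / sp
}

#' Propensity-score matching of cases to controls
#'
#' Fits a logistic propensity model of case status on the two stated
#' covariates (discharge date, days to event or window end), then
#' greedily matches each case (descending propensity, ties by record
#' id) to its `control_ratio` nearest controls on the logit scale,
#' without replacement. Under a degenerate propensity fit (perfect
#' separation), matching falls back to Euclidean distance on
#' standardized covariates, with a warning.
#'
#' @param cases,controls data.frames with columns `record_id`,
#'   `patient_id`, `discharge_date`, `days_to_event`.
#' @param config a [match_config()].
#' @param window_days prediction window recorded in the result.
#' @return object of class `case_control_dataset`: `$records` (columns
#'   `record_id`, `patient_id`, `label`, `match_group`, `window`),
#'   `$smd` (per-covariate standardized mean differences before/after),
#'   `$config`.
#' @export
propensity_match <- function(cases, controls, config = match_config(),
                             window_days = 365L) {
  r <- config$control_ratio
  if (nrow(controls) < r * nrow(cases))
    stopf("insufficient controls: need %d (= %d cases x %d), have %d",
          r * nrow(cases), nrow(cases), r, nrow(controls))
  covars <- c("discharge_date", "days_to_event")
  df <- rbind(cbind(cases[c("record_id", "patient_id", covars)], case = 1L),
              cbind(controls[c("record_id", "patient_id", covars)], case = 0L))

  fit <- suppressWarnings(stats::glm(
    case ~ discharge_date + days_to_event, family = stats::binomial(), data = df))
  p <- fit$fitted.values
  eps <- 1e-10
  degenerate <- !fit$converged || any(!is.finite(stats::coef(fit))) ||
    mean(p < eps | p > 1 - eps) > 0.5
  if (degenerate) {
    warnf("degenerate propensity model (separation); falling back to standardized covariate-distance matching")
    zs <- scale(df[covars])
    zs[is.nan(zs)] <- 0
    score_case <- rowSums(zs[df$case == 1L, , drop = FALSE]^2)  # ordering only
    dist_fun <- function(i_case, ctrl_idx) {
      d <- sweep(zs[ctrl_idx, , drop = FALSE], 2, zs[i_case, ], "-")
      sqrt(rowSums(d^2))
    }
  } else {
    lp <- clamp(p, eps, 1 - eps)
    lgt <- logit(lp)
    score_case <- lgt[df$case == 1L]
    dist_fun <- function(i_case, ctrl_idx) abs(lgt[ctrl_idx] - lgt[i_case])
  }

  case_idx <- which(df$case == 1L)
  ctrl_idx <- which(df$case == 0L)
  # greedy order: descending case score, tie-break lexicographic record id
  ord <- order(-score_case, df$record_id[case_idx])
  available <- rep(TRUE, length(ctrl_idx))
  groups <- vector("list", length(case_idx))
  for (gi in seq_along(ord)) {
    ci <- case_idx[ord[gi]]
    avail <- ctrl_idx[available]
    d <- dist_fun(ci, avail)
    if (!is.null(config$caliper)) {
      ok <- d <= config$caliper
      if (sum(ok) < r)
        stopf("case %s: only %d control(s) within caliper %.4g, need %d",
              df$record_id[ci], sum(ok), config$caliper, r)
      avail <- avail[ok]; d <- d[ok]
    }
    pick <- avail[order(d, df$record_id[avail])[seq_len(r)]]
    available[match(pick, ctrl_idx)] <- FALSE
    groups[[ord[gi]]] <- c(ci, pick)
  }

  rows <- do.call(rbind, lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    data.frame(record_id = df$record_id[idx],
               patient_id = df$patient_id[idx],
               label = c(1L, rep(0L, r)),
               match_group = g,
               window = as.integer(window_days),
               stringsAsFactors = FALSE)
  }))
  matched_ctrl <- df[unlist(lapply(groups, `[`, -1)), ]
  smd <- data.frame(
    covariate = covars,
    before = vapply(covars, function(v)
      standardized_mean_diff(df[[v]][case_idx], df[[v]][ctrl_idx]), 0),
    after = vapply(covars, function(v)
      standardized_mean_diff(df[[v]][case_idx], matched_ctrl[[v]]), 0),
    row.names = NULL)
  structure(list(records = rows, smd = smd, config = config,
                 window_days = as.integer(window_days)),
            class = "case_control_dataset")
}

#' Build a matched case-control cohort from timelines
#'
#' Applies, in order: per-patient 7-day repeat merging
#' ([merge_repeats()]), window labelling with prior-event exclusion
#' ([label_window()]), and propensity matching
#' ([propensity_match()]). Every input record is classified exactly once
#' (case, control, excluded, or merged away); the counts are returned as
#' provenance.
#'
#' @param timelines list of `patient_timeline`.
#' @param window_days prediction window (30, 180 or 365).
#' @param config a [match_config()].
#' @param code_sets an [outcome_code_sets()].
#' @return a `case_control_dataset` with an additional `$provenance`
#'   count table and `$labels` (the pre-matching classification of every
#'   record).
#' @export
build_cohort <- function(timelines, window_days = 365L,
                         config = match_config(),
                         code_sets = outcome_code_sets()) {
  lab_rows <- list()
  n_merged <- 0L
  for (tl in timelines) {
    kept <- merge_repeats(tl$admissions)
    n_merged <- n_merged + length(tl$admissions) - length(kept)
    for (rec in kept) {
      lab <- label_window(tl, rec, window_days, code_sets)
      lab_rows[[length(lab_rows) + 1L]] <- data.frame(
        record_id = rec$record_id, patient_id = rec$patient_id,
        discharge_date = rec$discharge_date, status = lab$status,
        reason = lab$reason, days_to_event = lab$days_to_event,
        stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, lab_rows)
  cases <- labels[labels$status == "case", ]
  controls <- labels[labels$status == "control", ]
  if (!nrow(cases)) stopf("no cases found for window %d", window_days)
  ds <- propensity_match(cases, controls, config, window_days)
  ds$labels <- labels
  ds$provenance <- c(
    input_records = sum(vapply(timelines, function(tl) length(tl$admissions), 0L)),
    merged_away = n_merged,
    cases = nrow(cases),
    control_eligible = nrow(controls),
    excluded_prior_event = sum(labels$status == "excluded"),
    matched_controls = sum(ds$records$label == 0L),
    unmatched_controls = nrow(controls) - sum(ds$records$label == 0L))
  ds
}

#' Write a matched cohort to CSV
#' @param dataset a `case_control_dataset`.
#' @param path CSV path; the provenance report is written alongside as
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  utils::write.csv(dataset$records, path, row.names = FALSE)
  jsonlite::write_json(
    list(provenance = as.list(dataset$provenance), smd = dataset$smd,
         window_days = dataset$window_days),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
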