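mk_rec <- function(id, pid, discharge, admit = max(0, discharge - 2))
  discharge_record(id, pid, admit, discharge, 60, "F",
                   labs = c(lab_01 = 1))

mk_tl <- function(pid, discharges, events = list()) {
  recs <- lapply(seq_along(discharges), function(i)
    mk_rec(sprintf("%s-%d", pid, i), pid, discharges[i]))
  structure(list(patient_id = pid, admissions = recs,
                 outcome_events = events), class = "patient_timeline")
}

ev <- function(date, kind, code) list(date = date, kind = kind, code = code)

test_that("outcome code matching is prefix-based, case-insensitive and dot-tolerant", {
  expect_true(is_outcome_code("F32.1", "diagnosis"))
  expect_true(is_outcome_code("f331", "diagnosis"))
  expect_true(is_outcome_code("F06.3", "diagnosis"))
  expect_true(is_outcome_code("F063x", "diagnosis"))
  expect_false(is_outcome_code("F06", "diagnosis"))   # F06.3/F06.4 only
  expect_false(is_outcome_code("F50", "diagnosis"))
  expect_true(is_outcome_code("N06AB03", "medication"))
  expect_true(is_outcome_code("n05ba01", "medication"))
  expect_false(is_outcome_code("N05C", "medication"))
  expect_false(is_outcome_code("F32", "medication"))  # ICD not an ATC
})

test_that("window labelling follows the case / prior-exclusion / control rules", {
  tl <- mk_tl("P1", 100, list(ev(200, "diagnosis", "F32.1")))
  rec <- tl$admissions[[1]]
  expect_identical(label_window(tl, rec, 365)$status, "case")
  expect_identical(label_window(tl, rec, 365)$days_to_event, 100L)
  # same event, 30-day window: outside, and not prior
  expect_identical(label_window(tl, rec, 30)$status, "control")

  tl2 <- mk_tl("P2", 100, list(ev(0, "medication", "N06AB03")))
  lab <- label_window(tl2, tl2$admissions[[1]], 365)
  expect_identical(lab$status, "excluded")
  expect_identical(lab$reason, "prior_event")

  # exactly 183 days prior is excluded; 184 is not
  tl3 <- mk_tl("P3", 200, list(ev(17, "diagnosis", "F40.0")))
  expect_identical(label_window(tl3, tl3$admissions[[1]], 365)$status, "excluded")
  tl4 <- mk_tl("P4", 201, list(ev(17, "diagnosis", "F40.0")))
  expect_identical(label_window(tl4, tl4$admissions[[1]], 365)$status, "control")

  # window boundary is half-open: event at discharge+window is a case,
  # at discharge is excluded
  tl5 <- mk_tl("P5", 100, list(ev(130, "diagnosis", "F41.1")))
  expect_identical(label_window(tl5, tl5$admissions[[1]], 30)$status, "case")
  tl6 <- mk_tl("P6", 100, list(ev(100, "diagnosis", "F41.1")))
  expect_identical(label_window(tl6, tl6$admissions[[1]], 30)$status, "excluded")

  # non-outcome codes are ignored
  tl7 <- mk_tl("P7", 100, list(ev(150, "diagnosis", "E11.9")))
  expect_identical(label_window(tl7, tl7$admissions[[1]], 365)$status, "control")
})

test_that("7-day repeat merging keeps the latest record of each chained cluster", {
  tl <- mk_tl("P1", c(0, 3, 20))
  kept <- merge_repeats(tl$admissions)
  expect_identical(vapply(kept, function(r) r$discharge_date, 0L), c(3L, 20L))

  tl2 <- mk_tl("P2", c(0, 6, 12))  # chained transitively
  kept2 <- merge_repeats(tl2$admissions)
  expect_identical(vapply(kept2, function(r) r$discharge_date, 0L), 12L)

  single <- mk_tl("P3", 5)$admissions
  expect_identical(merge_repeats(single), single)

  tl4 <- mk_tl("P4", c(0, 8, 16))  # gaps of 8 never merge
  expect_length(merge_repeats(tl4$admissions), 3)
})

test_that("matching returns exactly control_ratio controls per case", {
  set.seed(11)
  cases <- data.frame(record_id = sprintf("c%02d", 1:10),
                      patient_id = sprintf("pc%02d", 1:10),
                      discharge_date = sample(100:500, 10),
                      days_to_event = sample(1:365, 10))
  controls <- data.frame(record_id = sprintf("k%03d", 1:100),
                         patient_id = sprintf("pk%03d", 1:100),
                         discharge_date = sample(100:500, 100),
                         days_to_event = sample(1:365, 100))
  ds <- propensity_match(cases, controls, match_config(control_ratio = 3))
  expect_equal(sum(ds$records$label == 0), 30)
  expect_equal(sum(ds$records$label == 1), 10)
  tab <- table(ds$records$match_group)
  expect_true(all(tab == 4))
  expect_false(any(duplicated(ds$records$record_id)))

  expect_error(propensity_match(cases, controls[1:20, ], match_config(3)),
               "insufficient controls")
})

test_that("controls identical to cases on covariates still match exactly", {
  cases <- data.frame(record_id = c("c1", "c2"), patient_id = c("p1", "p2"),
                      discharge_date = c(100, 100), days_to_event = c(50, 50))
  controls <- data.frame(record_id = sprintf("k%d", 1:8),
                         patient_id = sprintf("q%d", 1:8),
                         discharge_date = 100, days_to_event = 50)
  ds <- suppressWarnings(propensity_match(cases, controls, match_config(3)))
  expect_equal(sum(ds$records$label == 0), 6)
  expect_true(all(table(ds$records$match_group) == 4))
})

test_that("greedy matching equals the exhaustive nearest-logit oracle", {
  cases <- data.frame(record_id = c("caseA", "caseB"),
                      patient_id = c("pa", "pb"),
                      discharge_date = c(120, 300),
                      days_to_event = c(40, 200))
  controls <- data.frame(record_id = sprintf("ctl%02d", 1:10),
                         patient_id = sprintf("pc%02d", 1:10),
                         discharge_date = c(110, 150, 250, 310, 90, 305, 130, 280, 200, 330),
                         days_to_event = c(50, 70, 180, 210, 30, 190, 45, 160, 120, 220))
  cfg <- match_config(control_ratio = 3)
  ds <- propensity_match(cases, controls, cfg)

  # oracle: fit the same logistic model, then exhaustively pick, for
  # each case in descending-propensity order, the 3 closest logits
  df <- rbind(cbind(cases, case = 1), cbind(controls, case = 0))
  fit <- suppressWarnings(
    stats::glm(case ~ discharge_date + days_to_event, binomial(), df))
  lgt <- stats::qlogis(pmin(pmax(fit$fitted.values, 1e-10), 1 - 1e-10))
  case_l <- lgt[df$case == 1]; ctrl_l <- lgt[df$case == 0]
  names(case_l) <- cases$record_id; names(ctrl_l) <- controls$record_id
  picked <- list()
  remaining <- ctrl_l
  for (ci in order(-case_l)) {
    d <- abs(remaining - case_l[ci])
    sel <- names(sort(d))[1:3]
    picked[[names(case_l)[ci]]] <- sort(sel)
    remaining <- remaining[setdiff(names(remaining), sel)]
  }
  got <- lapply(split(ds$records$record_id[ds$records$label == 0],
                      ds$records$match_group[ds$records$label == 0]),
                sort)
  case_of_group <- ds$records$record_id[ds$records$label == 1]
  for (g in seq_along(case_of_group))
    expect_identical(got[[as.character(g)]], unname(picked[[case_of_group[g]]]))
})

test_that("every record is classified exactly once and windows nest", {
  w <- small_world()
  statuses <- list()
  for (win in c(30, 180, 365)) {
    rows <- list()
    for (tl in w$timelines) {
      kept <- merge_repeats(tl$admissions)
      for (rec in kept)
        rows[[length(rows) + 1]] <- data.frame(
          id = rec$record_id, status = label_window(tl, rec, win)$status)
    }
    statuses[[as.character(win)]] <- do.call(rbind, rows)
  }
  n_kept <- nrow(statuses[["30"]])
  n_all <- sum(vapply(w$timelines, function(tl) length(tl$admissions), 0L))
  expect_lte(n_kept, n_all)
  for (s in statuses) {
    expect_equal(nrow(s), n_kept)
    expect_true(all(s$status %in% c("case", "control", "excluded")))
  }
  case30 <- statuses[["30"]]$id[statuses[["30"]]$status == "case"]
  case180 <- statuses[["180"]]$id[statuses[["180"]]$status == "case"]
  case365 <- statuses[["365"]]$id[statuses[["365"]]$status == "case"]
  expect_true(all(case30 %in% case180))
  expect_true(all(case180 %in% case365))
})

test_that("cohort building reports conservation in its provenance", {
  w <- strong_world()
  pr <- w$cohort$provenance
  expect_equal(pr[["input_records"]],
               pr[["merged_away"]] + pr[["cases"]] + pr[["control_eligible"]] +
                 pr[["excluded_prior_event"]])
  expect_equal(pr[["control_eligible"]],
               pr[["matched_controls"]] + pr[["unmatched_controls"]])
  expect_equal(pr[["matched_controls"]], 3 * pr[["cases"]])
})
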