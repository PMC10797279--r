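test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_patients = 0), "counts")
  expect_error(synthetic_config(missing_rate = 1.2), "probabilities")
  expect_error(synthetic_config(signal_strength = -1), "nonnegative")
  expect_error(synthetic_config(outcome_latent_weight = c(1, 2)), "latent_dim")
  expect_error(synthetic_config(n_diagnosis_codes = 5), "outcome ICD")
  expect_error(synthetic_config(n_medication_codes = 2), "outcome ATC")
})

test_that("generation is deterministic and byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_patients = 25, seed = 17)
  t1 <- generate_timelines(cfg)
  t2 <- generate_timelines(cfg)
  expect_identical(serialize(t1, NULL, version = 2),
                   serialize(t2, NULL, version = 2))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_timelines(t1, f1); write_timelines(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("timelines satisfy their structural invariants", {
  cfg <- synthetic_config(n_patients = 40, seed = 3)
  tls <- generate_timelines(cfg)
  for (tl in tls) {
    dd <- vapply(tl$admissions, function(r) r$discharge_date, 0L)
    expect_false(is.unsorted(dd))
    for (r in tl$admissions) {
      expect_lte(r$admit_date, r$discharge_date)
      expect_gte(r$admit_date, 0)
      expect_lte(length(r$history_tokens), cfg$max_history_len)
      expect_named(r$labs, sprintf("lab_%02d", 1:12))
    }
    for (e in tl$outcome_events)
      expect_true(is_outcome_code(e$code, e$kind))
  }
})

test_that("no-signal outcome rate matches the base hazard", {
  cfg <- synthetic_config(n_patients = 400, signal_strength = 0,
                          outcome_base_hazard = 0.12, seed = 13)
  rs <- latent_risk_scores(generate_timelines(cfg), cfg)
  n <- nrow(rs)
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(mean(rs$outcome) - 0.12), 3 * se)
})

test_that("true latent risk discriminates strongly under the strong-signal condition", {
  w <- strong_world()
  rs <- latent_risk_scores(w$timelines, w$cfg)
  expect_gte(nrow(rs), 2000)
  expect_gte(auc_roc(rs$outcome, rs$score), 0.85)
})

test_that("stronger outcome weights cannot reduce the ground-truth AUC", {
  scales <- c(0.2, 0.5, 1.0)
  mean_auc <- vapply(scales, function(sc) {
    mean(vapply(1:5, function(s) {
      cfg <- synthetic_config(n_patients = 300, signal_strength = 1,
                              outcome_latent_weight = rep(sc, 4),
                              outcome_base_hazard = 0.1, seed = 1000 + s)
      rs <- latent_risk_scores(generate_timelines(cfg), cfg)
      auc_roc(rs$outcome, rs$score)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_auc) >= -0.03))
})

test_that("JSONL write/read is an exact round trip", {
  cfg <- synthetic_config(n_patients = 15, seed = 5)
  tls <- generate_timelines(cfg)
  f <- withr::local_tempfile()
  write_timelines(tls, f)
  back <- read_timelines(f)
  expect_identical(back, lapply(tls, identity))  # attributes dropped

  write_timelines(list(), f)
  expect_identical(read_timelines(f), list())
})

test_that("a hand-written JSONL fixture parses field-for-field", {
  f <- withr::local_tempfile()
  writeLines(paste0(
    '{"patient_id":"PX","admissions":[',
    '{"record_id":"PX-1","patient_id":"PX","admit_date":10,"discharge_date":12,',
    '"age":70,"sex":"F","marital_status":"widowed",',
    '"labs":{"lab_01":1.5,"lab_02":null},"history_tokens":["hx_001","hx_001"],',
    '"diagnosis_codes":["F32.1"],"medication_codes":[]}],',
    '"outcome_events":[{"date":100,"kind":"medication","code":"N06AB03"}]}'), f)
  tl <- read_timelines(f)
  expect_length(tl, 1)
  r <- tl[[1]]$admissions[[1]]
  expect_identical(r$record_id, "PX-1")
  expect_identical(r$labs, c(lab_01 = 1.5, lab_02 = NA_real_))
  expect_identical(r$history_tokens, c("hx_001", "hx_001"))
  expect_identical(r$medication_codes, character(0))
  expect_identical(tl[[1]]$outcome_events[[1]],
                   list(date = 100L, kind = "medication", code = "N06AB03"))
})

test_that("malformed JSONL is reported with its line number", {
  f <- withr::local_tempfile()
  writeLines(c('{"patient_id":"A","admissions":[],"outcome_events":[]}',
               '{not json'), f)
  expect_error(read_timelines(f), "line 2")
})
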