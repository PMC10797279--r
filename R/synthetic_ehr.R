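#' Configuration for the synthetic EHR generator
#'
#' Builds a validated configuration for [generate_timelines()]. The
#' generator plants a per-patient latent state \eqn{z \sim N(0, I)} of
#' dimension `latent_dim` that jointly drives laboratory values, history
#' tokens, discharge diagnosis codes, medication codes and the
#' post-discharge depression/anxiety hazard, so every downstream stage
#' (contrastive pre-training, cohort construction, fine-tuning) has
#' learnable signal with verifiable ground truth.
#'
#' @param n_patients number of patients.
#' @param admissions_min,admissions_max inclusive range of admissions per
#'   patient.
#' @param n_lab_features number of numeric laboratory features.
#' @param history_vocab_size size of the history-token vocabulary.
#' @param n_diagnosis_codes,n_medication_codes sizes of the diagnosis and
#'   medication code universes. Must be at least as large as the built-in
#'   depression/anxiety outcome code sets (11 ICD-10-style codes, 4
#'   ATC-style codes) which are always embedded in the universes so the
#'   cohort labeller can find them.
#' @param latent_dim dimension of the latent patient state.
#' @param signal_strength nonnegative scale applied to every latent
#'   effect: shifts of labs, token/code sampling logits, and the latent
#'   contribution to the outcome hazard. `0` removes all planted signal.
#' @param outcome_base_hazard baseline probability of a
#'   depression/anxiety event within 365 days of a discharge, for a
#'   patient with `z = 0` (or `signal_strength = 0`).
#' @param outcome_latent_weight numeric vector of length `latent_dim`;
#'   log-odds contribution of each latent coordinate to the outcome.
#' @param missing_rate per-cell probability that a lab value is missing.
#' @param outlier_rate per-cell probability that a lab value is replaced
#'   by a gross outlier (8--12 noise SDs away).
#' @param max_history_len maximum history-token sequence length.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 500,
                             admissions_min = 1,
                             admissions_max = 3,
                             n_lab_features = 12,
                             history_vocab_size = 200,
                             n_diagnosis_codes = 40,
                             n_medication_codes = 25,
                             latent_dim = 4,
                             signal_strength = 1,
                             outcome_base_hazard = 0.03,
                             outcome_latent_weight = rep(0.5, latent_dim),
                             missing_rate = 0.05,
                             outlier_rate = 0.02,
                             max_history_len = 20,
                             seed = 1L) {
  counts <- c(n_patients = n_patients, admissions_min = admissions_min,
              admissions_max = admissions_max, n_lab_features = n_lab_features,
              history_vocab_size = history_vocab_size,
              n_diagnosis_codes = n_diagnosis_codes,
              n_medication_codes = n_medication_codes,
              latent_dim = latent_dim, max_history_len = max_history_len)
  if (any(counts < 1)) stopf("all counts must be positive")
  if (admissions_min > admissions_max) stopf("admissions_min > admissions_max")
  for (p in c(outcome_base_hazard, missing_rate, outlier_rate))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (signal_strength < 0) stopf("signal_strength must be nonnegative")
  if (length(outcome_latent_weight) != latent_dim)
    stopf("outcome_latent_weight must have length latent_dim (%d)", latent_dim)
  uni <- outcome_code_universe()
  if (n_diagnosis_codes < length(uni$icd))
    stopf("n_diagnosis_codes (%d) smaller than the outcome ICD code set (%d)",
          n_diagnosis_codes, length(uni$icd))
  if (n_medication_codes < length(uni$atc))
    stopf("n_medication_codes (%d) smaller than the outcome ATC code set (%d)",
          n_medication_codes, length(uni$atc))
  structure(list(
    n_patients = as.integer(n_patients),
    admissions_min = as.integer(admissions_min),
    admissions_max = as.integer(admissions_max),
    n_lab_features = as.integer(n_lab_features),
    history_vocab_size = as.integer(history_vocab_size),
    n_diagnosis_codes = as.integer(n_diagnosis_codes),
    n_medication_codes = as.integer(n_medication_codes),
    latent_dim = as.integer(latent_dim),
    signal_strength = signal_strength,
    outcome_base_hazard = outcome_base_hazard,
    outcome_latent_weight = as.numeric(outcome_latent_weight),
    missing_rate = missing_rate,
    outlier_rate = outlier_rate,
    max_history_len = as.integer(max_history_len),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Concrete instantiations of the depression/anxiety outcome code
# prefixes (ICD-10 F31-F34, F39, F06.3; F40-F43, F06.4; ATC N06A, N05B):
# one concrete code per prefix, always embedded in the generator's code
# universes.
outcome_code_universe <- function() {
  list(
    icd = c("F31.0", "F32.1", "F33.2", "F34.1", "F39", "F06.3",
            "F40.0", "F41.1", "F42.2", "F43.1", "F06.4"),
    atc = c("N06AB03", "N06AX16", "N05BA01", "N05BE01")
  )
}

# Full code universes of the generator: the outcome codes first, then
# neutral filler codes.
synthetic_code_universes <- function(config) {
  uni <- outcome_code_universe()
  n_extra_d <- config$n_diagnosis_codes - length(uni$icd)
  n_extra_m <- config$n_medication_codes - length(uni$atc)
  list(
    diagnosis = c(uni$icd, if (n_extra_d > 0) sprintf("E%02d.%d", seq_len(n_extra_d), seq_len(n_extra_d) %% 10)),
    medication = c(uni$atc, if (n_extra_m > 0) sprintf("A10B%s%02d", LETTERS[(seq_len(n_extra_m) %% 26) + 1], seq_len(n_extra_m)))
  )
}

#' Generate synthetic patient timelines
#'
#' Draws seeded synthetic hospital timelines. Each patient has a latent
#' vector `z`; lab values are linear in `z` plus unit-variance noise
#' (with planted gross outliers and missingness); history tokens,
#' diagnosis codes and medication codes are drawn from softmax
#' distributions whose logits are linear in `z`; a post-discharge
#' depression/anxiety event occurs with probability
#' `plogis(qlogis(outcome_base_hazard) + signal_strength * w %*% z)` and,
#' when it occurs, is placed at a uniform random day within 365 days
#' after discharge with a code from the depression/anxiety code sets.
#'
#' Ground truth (per-patient latent vectors, per-record event
#' probabilities and realized events) is attached as
#' `attr(result, "ground_truth")` and is intended for oracle tests only;
#' it is never consumed by the modelling pipeline.
#'
#' @param config a [synthetic_config()].
#' @return a list of `patient_timeline` objects with attribute
#'   `ground_truth`.
#' @export
generate_timelines <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(config$seed, generate_timelines_impl(config))
}

generate_timelines_impl <- function(config) {
  s <- config$signal_strength
  d <- config$latent_dim
  codes <- synthetic_code_universes(config)
  lab_names <- sprintf("lab_%02d", seq_len(config$n_lab_features))
  vocab <- sprintf("hx_%03d", seq_len(config$history_vocab_size))
  marital_levels <- c("married", "single", "widowed", "divorced")

  # population-level factor loadings, fixed per config seed
  lab_load <- matrix(rnorm(config$n_lab_features * d, sd = 0.8),
                     config$n_lab_features, d)
  tok_load <- matrix(rnorm(config$history_vocab_size * d, sd = 0.8),
                     config$history_vocab_size, d)
  dia_load <- matrix(rnorm(config$n_diagnosis_codes * d, sd = 0.8),
                     config$n_diagnosis_codes, d)
  med_load <- matrix(rnorm(config$n_medication_codes * d, sd = 0.8),
                     config$n_medication_codes, d)
  w <- config$outcome_latent_weight
  base_logit <- logit(clamp(config$outcome_base_hazard, 1e-6, 1 - 1e-6))

  timelines <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    z <- rnorm(d)
    n_adm <- sample_int_range(config$admissions_min, config$admissions_max)
    age0 <- round(clamp(rnorm(1, 62, 12), 25, 90))
    sex <- sample(c("F", "M"), 1)
    marital <- sample(marital_levels, 1)
    admit <- sample(200:1500, 1)

    admissions <- vector("list", n_adm)
    events <- list()
    rec_truth <- vector("list", n_adm)
    for (k in seq_len(n_adm)) {
      los <- sample(3:21, 1)
      discharge <- admit + los
      labs <- as.numeric(s * lab_load %*% z + rnorm(config$n_lab_features))
      out_mask <- runif(config$n_lab_features) < config$outlier_rate
      if (any(out_mask))
        labs[out_mask] <- labs[out_mask] +
          sample(c(-1, 1), sum(out_mask), TRUE) * runif(sum(out_mask), 8, 12)
      miss_mask <- runif(config$n_lab_features) < config$missing_rate
      labs[miss_mask] <- NA_real_
      names(labs) <- lab_names

      n_tok <- min(config$max_history_len, 5 + stats::rpois(1, 5))
      toks <- sample(vocab, n_tok, replace = TRUE,
                     prob = softmax(s * as.numeric(tok_load %*% z)))
      n_dia <- sample(1:5, 1)
      dia <- sample(codes$diagnosis, n_dia, replace = FALSE,
                    prob = softmax(s * as.numeric(dia_load %*% z)))
      n_med <- sample(1:4, 1)
      med <- sample(codes$medication, n_med, replace = FALSE,
                    prob = softmax(s * as.numeric(med_load %*% z)))

      rec <- discharge_record(
        record_id = sprintf("%s-A%02d", pid, k), patient_id = pid,
        admit_date = admit, discharge_date = discharge,
        age = age0 + (discharge - admit) %/% 365, sex = sex,
        marital_status = marital, labs = labs, history_tokens = toks,
        diagnosis_codes = sort(dia), medication_codes = sort(med))
      admissions[[k]] <- rec

      p_event <- stats::plogis(base_logit + s * sum(w * z))
      ev <- NULL
      if (runif(1) < p_event) {
        day <- discharge + sample(1:365, 1)
        if (runif(1) < 0.5) {
          ev <- list(date = day, kind = "diagnosis",
                     code = sample(outcome_code_universe()$icd, 1))
        } else {
          ev <- list(date = day, kind = "medication",
                     code = sample(outcome_code_universe()$atc, 1))
        }
        events[[length(events) + 1L]] <- ev
      }
      rec_truth[[k]] <- list(record_id = rec$record_id,
                             p_event = p_event,
                             event_day = if (is.null(ev)) NA_integer_ else ev$date)
      admit <- discharge + sample(30:300, 1)
    }
    ord <- order(vapply(admissions, function(r) r$discharge_date, 0),
                 vapply(admissions, function(r) r$record_id, ""))
    admissions <- admissions[ord]
    if (length(events))
      events <- events[order(vapply(events, function(e) e$date, 0))]
    timelines[[i]] <- structure(
      list(patient_id = pid, admissions = admissions,
           outcome_events = events),
      class = "patient_timeline")
    truth[[i]] <- list(patient_id = pid, z = z, records = rec_truth)
  }
  attr(timelines, "ground_truth") <- truth
  timelines
}

#' Construct a discharge record
#'
#' One hospitalization: demographics, labs, a history-token sequence,
#' diagnosis codes and medication codes, with integer day-index dates.
#'
#' @param record_id,patient_id opaque identifiers.
#' @param admit_date,discharge_date nonnegative integer day indices with
#'   `admit_date <= discharge_date`.
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param marital_status free categorical string.
#' @param labs named numeric vector (NA = missing).
#' @param history_tokens character vector (ordered).
#' @param diagnosis_codes,medication_codes character vectors of codes.
#' @return object of class `discharge_record`.
#' @export
discharge_record <- function(record_id, patient_id, admit_date,
                             discharge_date, age, sex,
                             marital_status = "unknown",
                             labs = numeric(0),
                             history_tokens = character(0),
                             diagnosis_codes = character(0),
                             medication_codes = character(0)) {
  if (admit_date > discharge_date) stopf("admit_date > discharge_date for %s", record_id)
  if (admit_date < 0) stopf("dates must be nonnegative day indices")
  if (!sex %in% c("F", "M")) stopf("sex must be 'F' or 'M'")
  structure(list(
    record_id = as.character(record_id),
    patient_id = as.character(patient_id),
    admit_date = as.integer(admit_date),
    discharge_date = as.integer(discharge_date),
    age = as.numeric(age), sex = sex,
    marital_status = as.character(marital_status),
    labs = labs,
    history_tokens = as.character(history_tokens),
    diagnosis_codes = as.character(diagnosis_codes),
    medication_codes = as.character(medication_codes)
  ), class = "discharge_record")
}

#' Print a patient timeline
#' @param x a `patient_timeline`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<patient_timeline %s: %d admissions, %d outcome events>\n",
              x$patient_id, length(x$admissions), length(x$outcome_events)))
  invisible(x)
}

# Flat list of all discharge records across timelines.
#' Extract all discharge records from a list of timelines
#' @param timelines list of `patient_timeline`.
#' @return flat list of `discharge_record`.
#' @export
all_records <- function(timelines) {
  unlist(lapply(timelines, function(tl) tl$admissions), recursive = FALSE)
}

#' True latent risk score of each record
#'
#' Bayes-optimal linear risk score `signal_strength * w'z` for each
#' record, computed from retained ground truth. Used by oracle tests to
#' bound achievable discrimination; not available to models.
#'
#' @param timelines output of [generate_timelines()].
#' @param config the generating [synthetic_config()].
#' @return data.frame with `record_id`, `score` (latent log-odds shift),
#'   `p_event`, and `outcome` (realized event within 365 days).
#' @export
latent_risk_scores <- function(timelines, config) {
  truth <- attr(timelines, "ground_truth")
  if (is.null(truth)) stopf("timelines carry no ground truth")
  rows <- lapply(truth, function(pt) {
    sc <- config$signal_strength * sum(config$outcome_latent_weight * pt$z)
    do.call(rbind, lapply(pt$records, function(r)
      data.frame(record_id = r$record_id, score = sc, p_event = r$p_event,
                 outcome = as.integer(!is.na(r$event_day)),
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}
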