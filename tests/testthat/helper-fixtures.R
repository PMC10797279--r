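# Shared fixtures, built once per test session and cached. The
# "strong world" is the strong-signal study condition (signal_strength
# 3, ~2000 records) used by the pre-training, fine-tuning and
# evaluation tests; the "small world" is a fast moderate-signal
# dataset for unit-level checks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_world <- function() memo("small", {
  cfg <- synthetic_config(n_patients = 60, signal_strength = 2, seed = 101)
  timelines <- generate_timelines(cfg)
  records <- all_records(timelines)
  schema <- fit_schema(records, n_bins = 6, embed_dim = 16)
  list(cfg = cfg, timelines = timelines, records = records,
       schema = schema, encoded = assemble_records(records, schema))
})

tiny_model_config <- function(seed = 5)
  dapcp_config(embed_dim = 16, proj_dim = 8, n_layers = 1, attn_dim = 8,
               expansion = 2, chunk_size = 8, temperature = 0.2,
               batch_size = 8, epochs = 1, seed = seed)

# Strong-signal study condition: ~2000 records with planted Bayes AUC
# around 0.93, the 365-day matched cohort, and a subcohort of the
# first 100 complete match groups used where full-cohort training
# would be wasteful.
strong_world <- function() memo("strong", {
  cfg <- synthetic_config(n_patients = 1000, admissions_min = 2,
                          admissions_max = 2, signal_strength = 3,
                          seed = 42)
  timelines <- generate_timelines(cfg)
  records <- screen_lab_outliers(all_records(timelines),
                                 contamination = 0.02, seed = 7)
  schema <- fit_schema(records, embed_dim = 32)
  cohort <- suppressWarnings(build_cohort(timelines, 365,
                                          match_config(seed = 7)))
  rec_by_id <- stats::setNames(records,
                               vapply(records, function(r) r$record_id, ""))
  cohort_records <- rec_by_id[cohort$records$record_id]
  cohort_encoded <- assemble_records(cohort_records, schema)
  sub <- which(cohort$records$match_group <= 100)
  list(cfg = cfg, timelines = timelines, records = records,
       schema = schema, cohort = cohort,
       cohort_records = cohort_records, cohort_encoded = cohort_encoded,
       cohort_labels = cohort$records$label,
       sub_idx = sub)
})

# Pre-trained checkpoint at the desk-scale dimensions (embed 32, 2
# layers, 5 epochs, contrastive batches of 8) on the full strong-world
# record set.
strong_checkpoint <- function() memo("strong_ckpt", {
  w <- strong_world()
  encoded <- assemble_records(w$records, w$schema)
  cfg <- dapcp_config(embed_dim = 32, proj_dim = 16, n_layers = 2,
                      attn_dim = 16, batch_size = 8, epochs = 5,
                      lr = 3e-3, seed = 42)
  pretrain(encoded, cfg, w$schema)
})

# One quick fine-tuned model on the subcohort, for prediction and
# interpretation tests.
strong_finetuned <- function() memo("strong_ft", {
  w <- strong_world()
  finetune(strong_checkpoint(), w$cohort_encoded[w$sub_idx],
           w$cohort_labels[w$sub_idx],
           dapft_config(epochs = 2, batch_size = 16, seed = 11))
})

# independent brute-force paired contrastive loss (direct softmax
# cross-entropy, scalar loops)
oracle_paired_loss <- function(x, m, d, tau) {
  K <- nrow(x)
  one <- function(a, b) {
    tot <- 0
    for (i in seq_len(K)) {
      sims <- numeric(K)
      for (j in seq_len(K)) sims[j] <- sum(a[i, ] * b[j, ]) / tau
      tot <- tot - log(exp(sims[i]) / sum(exp(sims)))
    }
    tot / K
  }
  one(x, m) + one(m, x) + one(x, d) + one(d, x)
}

rand_unit_rows <- function(n, p) {
  m <- matrix(stats::rnorm(n * p), n, p)
  m / sqrt(rowSums(m^2))
}

with_seed_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p)
}
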