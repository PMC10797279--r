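# End-to-end orchestration: generate -> preprocess -> cohorts ->
# pretrain -> finetune -> evaluate -> interpret, with one global seed
# fanned out to per-stage seeds and a manifest tracing every artifact
# to its config.

#' Default run configuration
#'
#' Nested stage configurations with a single global seed. Per-stage
#' seeds derive deterministically from the global seed and the stage
#' name, so any stage can be rerun in isolation.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for all artifacts.
#' @param generator a [synthetic_config()] (its `seed` is overridden by
#'   the derived stage seed).
#' @param window_days prediction window for cohort construction.
#' @param pretrain_config a [dapcp_config()].
#' @param finetune_config a [dapft_config()].
#' @param eval_models models passed to [kfold_evaluate()].
#' @param eval_k folds for evaluation.
#' @param n_bins,outlier_contamination preprocessing settings.
#' @param top_k features reported by interpretation.
#' @param ig_steps integrated-gradients path steps.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("dap-run-"),
                       generator = synthetic_config(),
                       window_days = 365L,
                       pretrain_config = dapcp_config(),
                       finetune_config = dapft_config(),
                       eval_models = c("dap", "logistic"),
                       eval_k = 5L, n_bins = 10L,
                       outlier_contamination = 0.02,
                       top_k = 20L, ig_steps = 50L) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 generator = generator, window_days = as.integer(window_days),
                 pretrain_config = pretrain_config,
                 finetune_config = finetune_config,
                 eval_models = eval_models, eval_k = as.integer(eval_k),
                 n_bins = as.integer(n_bins),
                 outlier_contamination = outlier_contamination,
                 top_k = as.integer(top_k), ig_steps = as.integer(ig_steps)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads the documented YAML layout (top-level `seed`, `out_dir`,
#' `window_days`, and optional `generator` / `pretrain` / `finetune` /
#' `evaluate` / `interpret` blocks whose keys override the
#' corresponding constructor defaults).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(ctor, block, extra = list()) {
    args <- c(extra, y[[block]] %||% list())
    do.call(ctor, args)
  }
  cfg <- run_config(
    seed = y$seed %||% 1L,
    out_dir = y$out_dir %||% tempfile("dap-run-"),
    generator = take(synthetic_config, "generator"),
    window_days = y$window_days %||% 365L,
    pretrain_config = take(dapcp_config, "pretrain"),
    finetune_config = take(dapft_config, "finetune"))
  for (nm in intersect(names(y), c("eval_models", "eval_k", "n_bins",
                                   "outlier_contamination", "top_k", "ig_steps")))
    cfg[[nm]] <- y[[nm]]
  cfg
}

content_hash <- function(path) {
  as.character(fnv1a_hash(paste(readLines(path, warn = FALSE), collapse = "\n")))
}

#' Run the full pipeline
#'
#' Executes generate, preprocess, cohort construction, contrastive
#' pre-training, fine-tuning, k-fold evaluation with decision-curve
#' analysis, and integrated-gradients interpretation; each stage writes
#' its artifact under `config$out_dir` and the manifest records the
#' stage seeds and content hashes.
#'
#' @param config a [run_config()].
#' @return the run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, path) {
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(config$seed, stage),
      path = basename(path), hash = content_hash(path))
  }
  stage <- "generate"
  res <- tryCatch({
    gen <- config$generator
    gen$seed <- as.integer(derive_seed(config$seed, "generate") %% 2147483647)
    timelines <- generate_timelines(gen)
    tl_path <- file.path(out, "timelines.jsonl")
    write_timelines(timelines, tl_path)
    write_ground_truth(timelines, file.path(out, "ground_truth.jsonl"))
    note("generate", tl_path)

    stage <- "preprocess"
    records <- all_records(timelines)
    records <- screen_lab_outliers(records, config$outlier_contamination,
                                   seed = as.integer(derive_seed(config$seed, "outliers") %% 2147483647))
    schema <- fit_schema(records, n_bins = config$n_bins,
                         embed_dim = config$pretrain_config$embed_dim)
    sc_path <- file.path(out, "schema.json")
    write_schema(schema, sc_path)
    note("preprocess", sc_path)

    stage <- "cohorts"
    cohort <- build_cohort(timelines, config$window_days,
                           match_config(seed = as.integer(derive_seed(config$seed, "match") %% 2147483647)))
    co_path <- file.path(out, "cohort.csv")
    write_cohort(cohort, co_path)
    note("cohorts", co_path)

    stage <- "pretrain"
    pc <- config$pretrain_config
    pc$seed <- as.integer(derive_seed(config$seed, "pretrain") %% 2147483647)
    encoded <- assemble_records(records, schema)
    ckpt <- pretrain(encoded, pc, schema)
    ck_path <- file.path(out, "checkpoint.json")
    write_checkpoint(ckpt, ck_path)
    note("pretrain", ck_path)

    stage <- "finetune"
    rec_by_id <- stats::setNames(records, vapply(records, function(r) r$record_id, ""))
    co_records <- rec_by_id[cohort$records$record_id]
    co_encoded <- assemble_records(co_records, schema)
    fc <- config$finetune_config
    fc$seed <- as.integer(derive_seed(config$seed, "finetune") %% 2147483647)
    ft <- finetune(ckpt, co_encoded, cohort$records$label, fc)
    ft_path <- file.path(out, "finetune_metrics.json")
    jsonlite::write_json(ft$metrics, ft_path, digits = I(17))
    note("finetune", ft_path)

    stage <- "evaluate"
    ev <- kfold_evaluate(co_records, cohort$records$label,
                         models = config$eval_models, k = config$eval_k,
                         seed = as.integer(derive_seed(config$seed, "evaluate") %% 2147483647),
                         checkpoint = ckpt, ft_config = fc)
    ev_path <- file.path(out, "metrics.json")
    jsonlite::write_json(list(folds = ev$folds, summary = ev$summary),
                         ev_path, digits = I(17))
    dca <- decision_curve(cohort$records$label,
                          ev$scores[[config$eval_models[[1]]]],
                          folds = ev$fold_id)
    utils::write.csv(dca, file.path(out, "dca.csv"), row.names = FALSE)
    note("evaluate", ev_path)

    stage <- "interpret"
    top <- top_features(ft, co_encoded[seq_len(min(25, length(co_encoded)))],
                        k = config$top_k, steps = config$ig_steps)
    ig_path <- file.path(out, "top_features.csv")
    utils::write.csv(top, ig_path, row.names = FALSE)
    note("interpret", ig_path)
    manifest
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  res$version <- as.character(utils::packageVersion("dapehr"))
  jsonlite::write_json(res, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  res
}
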