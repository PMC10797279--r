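# Evaluation: ROC-AUC / PR-AUC, fold-wise t-tests, stratified
# patient-disjoint k-fold cross-validation of the fine-tuned model
# against feature-vector baselines, and decision curve analysis.

#' ROC-AUC via the rank statistic
#'
#' Mann-Whitney formulation with ties sharing averaged ranks (a tied
#' positive/negative pair contributes 1/2).
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stopf("auc_roc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC by step integration
#'
#' Descending-score sweep over distinct thresholds (tied scores enter
#' together); the area is the sum of recall increments times the
#' precision at each threshold.
#'
#' @inheritParams auc_roc
#' @return PR-AUC in `(0, 1]`. Constant scores give the prevalence.
#' @export
auc_pr <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0 || P == length(labels)) stopf("auc_pr needs both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Welch t-test on two fold-metric vectors
#'
#' @param metric_vec_a,metric_vec_b equal-length (>= 2) vectors of
#'   per-fold metrics.
#' @param paired use the paired test (folds shared between models).
#' @return two-sided p-value. Two zero-variance vectors give 1 when
#'   their means are equal (indistinguishable) and 0 otherwise.
#' @export
compare_folds <- function(metric_vec_a, metric_vec_b, paired = FALSE) {
  if (length(metric_vec_a) != length(metric_vec_b) || length(metric_vec_a) < 2)
    stopf("fold metric vectors must have equal length >= 2")
  if (stats::var(metric_vec_a) == 0 && stats::var(metric_vec_b) == 0) {
    return(if (isTRUE(all.equal(mean(metric_vec_a), mean(metric_vec_b)))) 1 else 0)
  }
  stats::t.test(metric_vec_a, metric_vec_b, paired = paired)$p.value
}

#' Decision curve analysis
#'
#' Net benefit `TP/n - (FP/n) * t/(1-t)` across a grid of threshold
#' probabilities `t` (predicted positive when score >= t), with
#' treat-all and treat-none reference curves. With fold assignments the
#' fold-wise mean and standard deviation are returned per threshold.
#'
#' @param labels 0/1 labels.
#' @param scores predicted probabilities.
#' @param thresholds grid in (0, 1); values at or above 1 are rejected.
#' @param folds optional integer fold assignment per observation.
#' @return `net_benefit_curve`: data.frame with `threshold`, `curve`
#'   (`model`, `treat_all`, `treat_none`), `net_benefit` (mean across
#'   folds) and `sd`.
#' @export
decision_curve <- function(labels, scores,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           folds = NULL) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie strictly inside (0, 1)")
  nb_one <- function(y, s, t) {
    n <- length(y)
    pos <- s >= t
    tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
    tp / n - (fp / n) * t / (1 - t)
  }
  if (is.null(folds)) folds <- rep(1L, length(labels))
  fl <- unique(folds)
  per_fold <- function(fun) vapply(thresholds, function(t)
    c(mean = mean(vapply(fl, function(f) fun(labels[folds == f], scores[folds == f], t), 0)),
      sd = stats::sd(vapply(fl, function(f) fun(labels[folds == f], scores[folds == f], t), 0))),
    c(mean = 0, sd = 0))
  model <- per_fold(nb_one)
  all_ <- per_fold(function(y, s, t) nb_one(y, rep(1, length(y)), t))
  sd0 <- function(x) ifelse(is.na(x), 0, x)
  out <- rbind(
    data.frame(threshold = thresholds, curve = "model",
               net_benefit = model["mean", ], sd = sd0(model["sd", ])),
    data.frame(threshold = thresholds, curve = "treat_all",
               net_benefit = all_["mean", ], sd = sd0(all_["sd", ])),
    data.frame(threshold = thresholds, curve = "treat_none",
               net_benefit = 0, sd = 0))
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Patient-disjoint stratified fold assignment
#'
#' Patients (not records) are stratified by whether they contribute any
#' case record and dealt round-robin into `k` folds, so no patient
#' spans folds.
#'
#' @param patient_ids character vector per record.
#' @param labels 0/1 per record.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return integer fold id per record.
#' @export
make_patient_folds <- function(patient_ids, labels, k, seed = 1L) {
  pt_label <- tapply(as.integer(labels), patient_ids, max)
  fold_of <- with_rng(seed, {
    f <- integer(0); nm <- character(0)
    for (s in sort(unique(pt_label))) {
      ids <- sample(names(pt_label)[pt_label == s])
      f <- c(f, rep_len(seq_len(k), length(ids)))
      nm <- c(nm, ids)
    }
    stats::setNames(f, nm)
  })
  folds <- as.integer(fold_of[patient_ids])
  tab <- table(folds, labels)
  if (any(tab == 0))
    stopf("some fold lacks a class; reduce k or enlarge the dataset")
  folds
}

# --- baseline feature vectorization -------------------------------------

# mean-imputed structured features + TF-IDF bag over text-like fields
# (history tokens, diagnosis codes, medication codes). IDF and
# imputation means come from the training split only.
fit_vectorizer <- function(records) {
  labm <- lab_matrix(records)
  mu <- colMeans(labm, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  docs <- lapply(records, record_tokens)
  vocab <- sort(unique(unlist(docs)))
  df <- table(factor(unlist(lapply(docs, unique)), levels = vocab))
  idf <- log(length(docs) / (1 + as.numeric(df))) + 1
  marital_levels <- sort(unique(vapply(records, function(r) r$marital_status, "")))
  list(lab_names = colnames(labm), mu = mu, vocab = vocab, idf = idf,
       marital_levels = marital_levels)
}

record_tokens <- function(r)
  c(r$history_tokens, paste0("dx:", r$diagnosis_codes),
    paste0("rx:", r$medication_codes))

vectorize_records <- function(records, vz) {
  labm <- lab_matrix(records)
  missing_cols <- setdiff(vz$lab_names, colnames(labm))
  for (mc in missing_cols) {
    labm <- cbind(labm, NA_real_)
    colnames(labm)[ncol(labm)] <- mc
  }
  labm <- labm[, vz$lab_names, drop = FALSE]
  for (j in seq_along(vz$lab_names))
    labm[is.na(labm[, j]), j] <- vz$mu[[j]]
  demo <- t(vapply(records, function(r) c(
    age = r$age, male = as.numeric(r$sex == "M"),
    marital = as.numeric(match(r$marital_status, vz$marital_levels, nomatch = 0))),
    c(0, 0, 0)))
  tf <- matrix(0, length(records), length(vz$vocab),
               dimnames = list(NULL, vz$vocab))
  for (i in seq_along(records)) {
    tab <- table(factor(record_tokens(records[[i]]), levels = vz$vocab))
    tf[i, ] <- as.numeric(tab)
  }
  tfidf <- sweep(tf, 2, vz$idf, "*")
  cbind(demo, labm, tfidf)
}

fit_baseline <- function(model, x, y, seed) {
  switch(model,
    logistic = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
    },
    rf = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stopf("the random-forest baseline needs the 'ranger' package")
      ranger::ranger(y = factor(y), x = as.data.frame(x), probability = TRUE,
                     num.trees = 300, seed = seed)
    },
    xgb = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stopf("the gradient-boosting baseline needs the 'xgboost' package")
      dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
      xgboost::xgb.train(params = list(max_depth = 4, eta = 0.2,
                                       objective = "binary:logistic",
                                       nthread = 1),
                         data = dtrain, nrounds = 50, verbose = 0)
    },
    stopf("unknown baseline '%s'", model))
}

predict_baseline <- function(model, fit, x) {
  switch(model,
    logistic = as.numeric(suppressWarnings(
      stats::predict(fit, newdata = data.frame(x), type = "response"))),
    rf = ranger::predictions(stats::predict(fit, data = as.data.frame(x)))[, "1"],
    xgb = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(data = x))))
}

#' Stratified patient-disjoint k-fold evaluation
#'
#' Trains each requested model on k-1 folds and scores the held-out
#' fold with ROC-AUC and PR-AUC. `"dap"` fine-tunes the supplied
#' pre-trained checkpoint per fold; the baselines (`"logistic"`,
#' `"rf"`, `"xgb"`) consume mean-imputed structured features
#' concatenated with a TF-IDF bag over the record's token fields, both
#' fitted on the training folds only.
#'
#' @param records list of `discharge_record` (the matched cohort).
#' @param labels 0/1 outcome labels per record.
#' @param models character subset of `c("dap", "logistic", "rf",
#'   "xgb")`.
#' @param k number of folds (>= 2).
#' @param seed fold-assignment / training seed.
#' @param checkpoint `dapcp_model`, required when `"dap"` is requested.
#' @param ft_config [dapft_config()] for the per-fold fine-tuning.
#' @return object of class `fold_metrics`: `$folds` (model, fold,
#'   roc_auc, pr_auc), `$summary` (mean and sd per model), `$scores`
#'   (out-of-fold scores per model) and `$fold_id`.
#' @export
kfold_evaluate <- function(records, labels,
                           models = c("dap", "logistic", "rf", "xgb"),
                           k = 10L, seed = 1L, checkpoint = NULL,
                           ft_config = dapft_config()) {
  if (k < 2) stopf("k must be >= 2")
  labels <- as.integer(labels)
  pids <- vapply(records, function(r) r$patient_id, "")
  folds <- make_patient_folds(pids, labels, k, seed)
  if ("dap" %in% models && is.null(checkpoint))
    stopf("the 'dap' model needs a pre-trained checkpoint")
  rows <- list()
  scores <- lapply(models, function(m) rep(NA_real_, length(labels)))
  names(scores) <- models
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    vz <- fit_vectorizer(records[tr])
    xtr <- vectorize_records(records[tr], vz)
    xte <- vectorize_records(records[te], vz)
    for (m in models) {
      s <- if (m == "dap") {
        enc <- assemble_records(records, checkpoint$schema)
        cfg <- ft_config
        cfg$seed <- as.integer(derive_seed(seed, paste0("fold", f)) %% 2147483647)
        cfg$val_fraction <- 0
        fit <- finetune(checkpoint, enc[tr], labels[tr], cfg)
        as.numeric(stats::plogis(predict_logits(fit$params, enc[te],
                                                fit$encoder_config, fit$schema)))
      } else {
        fit <- fit_baseline(m, xtr, labels[tr],
                            seed = as.integer(derive_seed(seed, paste0(m, f)) %% 2147483647))
        predict_baseline(m, fit, xte)
      }
      scores[[m]][te] <- s
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, fold = f, roc_auc = auc_roc(labels[te], s),
        pr_auc = auc_pr(labels[te], s))
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(models, function(m) {
    sub <- per_fold[per_fold$model == m, ]
    data.frame(model = m, mean_roc_auc = mean(sub$roc_auc),
               sd_roc_auc = stats::sd(sub$roc_auc),
               mean_pr_auc = mean(sub$pr_auc),
               sd_pr_auc = stats::sd(sub$pr_auc))
  }))
  structure(list(folds = per_fold, summary = summary, scores = scores,
                 fold_id = folds, labels = labels),
            class = "fold_metrics")
}

#' External validation: train on one cohort, test on another
#'
#' Mirrors the regional-to-primary-care transfer setting: the model is
#' trained on resampled training-cohort folds while the external test
#' cohort stays fixed; fold-wise metrics on the test cohort are
#' returned.
#'
#' @param train_records,train_labels the training cohort.
#' @param test_records,test_labels the fixed external test cohort.
#' @param models,k,seed,checkpoint,ft_config as in [kfold_evaluate()].
#' @return a `fold_metrics` object (metrics computed on the external
#'   test set for each training resample).
#' @export
external_evaluate <- function(train_records, train_labels,
                              test_records, test_labels,
                              models = c("dap", "logistic"), k = 10L,
                              seed = 1L, checkpoint = NULL,
                              ft_config = dapft_config()) {
  train_labels <- as.integer(train_labels)
  test_labels <- as.integer(test_labels)
  pids <- vapply(train_records, function(r) r$patient_id, "")
  folds <- make_patient_folds(pids, train_labels, k, seed)
  rows <- list()
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    vz <- fit_vectorizer(train_records[tr])
    xtr <- vectorize_records(train_records[tr], vz)
    xte <- vectorize_records(test_records, vz)
    for (m in models) {
      s <- if (m == "dap") {
        enc_tr <- assemble_records(train_records[tr], checkpoint$schema)
        enc_te <- assemble_records(test_records, checkpoint$schema)
        cfg <- ft_config
        cfg$seed <- as.integer(derive_seed(seed, paste0("ext", f)) %% 2147483647)
        cfg$val_fraction <- 0
        fit <- finetune(checkpoint, enc_tr, train_labels[tr], cfg)
        as.numeric(stats::plogis(predict_logits(fit$params, enc_te,
                                                fit$encoder_config, fit$schema)))
      } else {
        fit <- fit_baseline(m, xtr, train_labels[tr],
                            seed = as.integer(derive_seed(seed, paste0(m, f)) %% 2147483647))
        predict_baseline(m, fit, xte)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, fold = f, roc_auc = auc_roc(test_labels, s),
        pr_auc = auc_pr(test_labels, s))
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(models, function(m) {
    sub <- per_fold[per_fold$model == m, ]
    data.frame(model = m, mean_roc_auc = mean(sub$roc_auc),
               sd_roc_auc = stats::sd(sub$roc_auc),
               mean_pr_auc = mean(sub$pr_auc),
               sd_pr_auc = stats::sd(sub$pr_auc))
  }))
  structure(list(folds = per_fold, summary = summary),
            class = "fold_metrics")
}
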