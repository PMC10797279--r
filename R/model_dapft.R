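# Fine-tuning of the pre-trained encoder for window-specific
# depression/anxiety prediction: the record triple (x, m, d) is
# concatenated and fed to a single affine head whose sigmoid output is
# trained with binary cross-entropy, end-to-end through the encoder.

#' Fine-tuning configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (constant; no schedule).
#' @param val_fraction fraction of patients held out for per-epoch
#'   validation metrics.
#' @param freeze_encoder if `TRUE`, only the prediction head is
#'   updated.
#' @param seed shuffling/split/initialization seed.
#' @return object of class `dapft_config`.
#' @export
dapft_config <- function(epochs = 5L, batch_size = 32L, lr = 3e-3,
                         val_fraction = 0.2, freeze_encoder = FALSE,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_fraction = val_fraction,
                 freeze_encoder = isTRUE(freeze_encoder),
                 seed = as.integer(seed)),
            class = "dapft_config")
}

#' Binary cross-entropy loss
#'
#' `sum_i -[ y_i log u_i + (1 - y_i) log(1 - u_i) ]` with predicted
#' probabilities clipped to `[eps, 1 - eps]`, `eps = 1e-7`.
#'
#' @param y 0/1 labels.
#' @param u predicted probabilities in `[0, 1]` (values outside error).
#' @return list with `sum` and `mean` of the per-pair terms.
#' @export
bce_loss <- function(y, u) {
  if (!length(y) || length(y) != length(u)) stopf("y and u must be nonempty and equal length")
  if (any(u < 0 | u > 1)) stopf("predicted probabilities outside [0, 1]")
  eps <- 1e-7
  uc <- clamp(u, eps, 1 - eps)
  terms <- -(y * log(uc) + (1 - y) * log(1 - uc))
  list(sum = sum(terms), mean = mean(terms))
}

init_head <- function(proj_dim, seed) {
  with_rng(derive_seed(seed, "head"), list(
    Wu = matrix(stats::rnorm(3 * proj_dim, sd = sqrt(2 / (3 * proj_dim + 1))),
                3 * proj_dim, 1),
    bu = matrix(0, 1, 1)))
}

# forward to logits; returns tape handles for training use
ft_forward <- function(tp, pid, batch, config) {
  out <- encoder_forward(tp, pid, batch, config)
  rep3 <- ad_cbind(tp, c(out$x, out$m, out$d))
  ad_add_bias(tp, ad_mm(tp, rep3, pid$Wu), pid$bu)
}

#' Fine-tune for post-discharge risk prediction
#'
#' Initializes the encoder from a pre-trained checkpoint (or randomly
#' with `init = "random"`), adds the single-layer prediction head over
#' the concatenated `[x, m, d]` representation, and trains end-to-end
#' with binary cross-entropy. A patient-disjoint stratified validation
#' split is scored with ROC-AUC and PR-AUC after every epoch.
#'
#' @param checkpoint a `dapcp_model` (from [pretrain()] or
#'   [read_checkpoint()]).
#' @param encoded_list list of `encoded_inputs` for the cohort records.
#' @param labels 0/1 outcome labels aligned with `encoded_list`.
#' @param config a [dapft_config()].
#' @param init `"pretrained"` (encoder weights from the checkpoint) or
#'   `"random"` (fresh initialization; ablation arm).
#' @return object of class `dapft_model`: `$params`, `$encoder_config`,
#'   `$schema`, `$metrics` (per-epoch train loss and validation
#'   ROC-AUC/PR-AUC).
#' @export
finetune <- function(checkpoint, encoded_list, labels,
                     config = dapft_config(),
                     init = c("pretrained", "random")) {
  init <- match.arg(init)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopf("label column is constant; fine-tuning task is degenerate")
  if (length(labels) != length(encoded_list)) stopf("labels misaligned")
  enc_cfg <- checkpoint$config
  schema <- checkpoint$schema
  enc_params <- if (init == "pretrained") checkpoint$params else
    init_dapcp_params(modify_seed(enc_cfg, derive_seed(config$seed, "reinit")), schema)
  params <- c(enc_params, init_head(enc_cfg$proj_dim, config$seed))
  state <- adam_state(params)
  skip <- if (config$freeze_encoder) setdiff(names(params), c("Wu", "bu")) else character(0)

  pids <- vapply(encoded_list, function(x) x$patient_id, "")
  val_idx <- stratified_patient_holdout(pids, labels, config$val_fraction,
                                        derive_seed(config$seed, "valsplit"))
  tr_idx <- setdiff(seq_along(labels), val_idx)
  if (length(unique(labels[tr_idx])) < 2 ||
      (length(val_idx) > 0 && length(unique(labels[val_idx])) < 2))
    stopf("train or validation split lost a class; enlarge the cohort")

  metrics <- data.frame()
  for (ep in seq_len(config$epochs)) {
    ord <- with_rng(derive_seed(config$seed, paste0("ft-shuffle", ep)),
                    sample(tr_idx))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      batch <- build_batch(encoded_list[b], enc_cfg, schema)
      tp <- ad_tape()
      pid <- push_params(tp, params)
      logits <- ft_forward(tp, pid, batch, enc_cfg)
      loss <- ad_bce_logits(tp, logits, labels[b])
      if (!is.finite(ad_value(tp, loss)[1]))
        stopf("fine-tuning loss diverged at epoch %d", ep)
      gl <- ad_backward(tp, loss)
      grads <- lapply(pid, function(i) gl[[i]])
      upd <- adam_step(params, clip_grads(grads), state, config$lr,
                       skip = skip)
      params <- upd$params; state <- upd$state
      losses <- c(losses, as.numeric(ad_value(tp, loss)))
    }
    if (length(val_idx)) {
      val_u <- predict_logits(params, encoded_list[val_idx], enc_cfg, schema)
      metrics <- rbind(metrics, data.frame(
        epoch = ep, train_loss = mean(losses),
        val_roc_auc = auc_roc(labels[val_idx], val_u),
        val_pr_auc = auc_pr(labels[val_idx], val_u)))
    } else {
      metrics <- rbind(metrics, data.frame(
        epoch = ep, train_loss = mean(losses),
        val_roc_auc = NA_real_, val_pr_auc = NA_real_))
    }
  }
  structure(list(params = params, encoder_config = enc_cfg,
                 schema = schema, metrics = metrics, init = init,
                 config = config),
            class = "dapft_model")
}

modify_seed <- function(cfg, seed) { cfg$seed <- as.integer(seed %% 2147483647); cfg }

# patient-disjoint stratified holdout: returns record indices
stratified_patient_holdout <- function(patient_ids, labels, fraction, seed) {
  if (fraction <= 0) return(integer(0))
  pt_label <- tapply(labels, patient_ids, max)
  with_rng(seed, {
    held <- character(0)
    for (s in unique(pt_label)) {
      ids <- names(pt_label)[pt_label == s]
      k <- max(1L, round(fraction * length(ids)))
      held <- c(held, sample(ids, k))
    }
    which(patient_ids %in% held)
  })
}

predict_logits <- function(params, encoded_list, enc_cfg, schema) {
  if (!length(encoded_list)) return(numeric(0))
  batch <- build_batch(encoded_list, enc_cfg, schema)
  tp <- ad_tape()
  pid <- push_params(tp, params)
  as.numeric(ad_value(tp, ft_forward(tp, pid, batch, enc_cfg)))
}

#' Predict post-discharge risk probabilities
#'
#' Deterministic (eval-mode) per-record probability via the sigmoid of
#' the fine-tuned head over `[x, m, d]`.
#'
#' @param model a `dapft_model`.
#' @param encoded_list list of `encoded_inputs` assembled with the
#'   model's training schema.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, encoded_list) {
  check_schema_compat(model$schema, encoded_list)
  u <- stats::plogis(predict_logits(model$params, encoded_list,
                                    model$encoder_config, model$schema))
  names(u) <- vapply(encoded_list, function(x) x$record_id, "")
  u
}

check_schema_compat <- function(schema, encoded_list) {
  for (x in encoded_list) {
    missing <- setdiff(schema$feature_names, x$feature_names)
    if (length(missing))
      stopf("record %s lacks schema feature(s): %s", x$record_id,
            paste(missing, collapse = ", "))
    extra <- setdiff(x$feature_names, schema$feature_names)
    if (length(extra))
      stopf("record %s has feature(s) unknown to the schema: %s",
            x$record_id, paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}
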