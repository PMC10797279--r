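# The contrastive pre-training model: a structured-slot transformer
# encoder, a gated single-head linear-attention (FLASH-style) fusion
# encoder over structured + history inputs, text encoders of the same
# structure for diagnosis and medication names, projection heads, and
# the paired InfoNCE loss that aligns the fused patient-state
# representation x with the medication (m) and diagnosis (d)
# representations of the same record.

#' Encoder configuration
#'
#' Desk-scale defaults. The production-scale preset of the original
#' design (24 layers, max length 2500, batch 6, lr 2e-5, 10 epochs) is
#' available as `dapcp_config(preset = "production")` but is not
#' exercised by the test suite.
#'
#' @param embed_dim embedding width of all encoders.
#' @param proj_dim dimension of the projected x/m/d vectors.
#' @param n_layers gated-attention blocks per encoder.
#' @param attn_dim shared low-rank dimension of the attention queries
#'   and keys.
#' @param expansion width multiplier of the gating branch.
#' @param chunk_size positions per quadratic-attention chunk; longer
#'   sequences mix across chunks through the linear-attention term.
#' @param max_seq_len hard cap on assembled sequence length; longer
#'   inputs are truncated with a warning.
#' @param temperature InfoNCE temperature tau (> 0).
#' @param batch_size contrastive batch size K.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed initialization/shuffling seed.
#' @param preset `"desk"` (default) or `"production"`.
#' @return object of class `dapcp_config`.
#' @export
dapcp_config <- function(embed_dim = 32L, proj_dim = 16L, n_layers = 2L,
                         attn_dim = 16L, expansion = 2L, chunk_size = 16L,
                         max_seq_len = 64L, temperature = 0.07,
                         batch_size = 16L, lr = 3e-3, epochs = 5L,
                         seed = 1L, preset = c("desk", "production")) {
  preset <- match.arg(preset)
  if (preset == "production") {
    n_layers <- 24L; max_seq_len <- 2500L; batch_size <- 6L
    lr <- 2e-5; epochs <- 10L
  }
  if (temperature <= 0) stopf("temperature must be > 0")
  if (embed_dim < 1 || proj_dim < 1 || n_layers < 1) stopf("invalid dimensions")
  structure(list(embed_dim = as.integer(embed_dim),
                 proj_dim = as.integer(proj_dim),
                 n_layers = as.integer(n_layers),
                 attn_dim = as.integer(attn_dim),
                 expansion = as.integer(expansion),
                 chunk_size = as.integer(chunk_size),
                 max_seq_len = as.integer(max_seq_len),
                 temperature = temperature,
                 batch_size = as.integer(batch_size),
                 lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed), preset = preset),
            class = "dapcp_config")
}

gau_param_names <- function(prefix, l) {
  paste0(prefix, ".", l, ".", c("gn", "Wz", "bz", "gq", "bq", "gk", "bk",
                                "Wu", "bu", "Wv", "bv", "Wo", "bo"))
}

init_gau <- function(d, e, h) {
  xav <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  list(gn = matrix(1, 1, d),
       Wz = xav(d, e), bz = matrix(0, 1, e),
       gq = matrix(1, 1, e), bq = matrix(0, 1, e),
       gk = matrix(1, 1, e), bk = matrix(0, 1, e),
       Wu = xav(d, h), bu = matrix(0, 1, h),
       Wv = xav(d, h), bv = matrix(0, 1, h),
       Wo = xav(h, d), bo = matrix(0, 1, d))
}

#' Initialize model parameters
#'
#' Flat named list of weight matrices for the structured encoder
#' (`psiE`), the fusion encoder (`fX`), the diagnosis and medication
#' text encoders (`fD`, `fM`), the learned bin-embedding table, the
#' null tokens for empty text fields, and the projection heads
#' `gx`/`gm`/`gd`. Identical seed gives identical initialization.
#'
#' @param config a [dapcp_config()].
#' @param schema the fitted `feature_schema` (for the bin count).
#' @return named list of numeric matrices.
#' @export
init_dapcp_params <- function(config, schema) {
  d <- config$embed_dim; e <- config$attn_dim
  h <- config$expansion * d; p <- config$proj_dim
  with_rng(derive_seed(config$seed, "init"), {
    xav <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
    params <- list(
      Wsn = xav(d, d),
      bin_table = matrix(stats::rnorm((schema$n_bins + 1L) * d, sd = 0.1),
                         schema$n_bins + 1L, d),
      Wn = xav(d, d), bn = matrix(0, 1, d), null_n = matrix(stats::rnorm(d, sd = 0.1), 1, d),
      Wdin = xav(d, d), bdin = matrix(0, 1, d), null_d = matrix(stats::rnorm(d, sd = 0.1), 1, d),
      Wmin = xav(d, d), bmin = matrix(0, 1, d), null_m = matrix(stats::rnorm(d, sd = 0.1), 1, d),
      Wx = xav(d, p), bx = matrix(0, 1, p),
      Wm = xav(d, p), bm = matrix(0, 1, p),
      Wd = xav(d, p), bd = matrix(0, 1, p))
    for (enc in c("psiE", "fX", "fD", "fM")) {
      for (l in seq_len(config$n_layers)) {
        g <- init_gau(d, e, h)
        names(g) <- gau_param_names(enc, l)
        params <- c(params, g)
      }
    }
    params
  })
}

# Stack a batch of encoded_inputs into the matrices the tape consumes.
build_batch <- function(encoded_list, config, schema) {
  K <- length(encoded_list)
  F_ <- length(schema$feature_names)
  name_mat <- do.call(rbind, lapply(encoded_list, function(x) x$name_embeds))
  bins <- unlist(lapply(encoded_list, function(x) x$bins), use.names = FALSE)
  stack_tokens <- function(field) {
    mats <- lapply(encoded_list, function(x) x[[field]])
    lens <- vapply(mats, nrow, 0L)
    over <- lens > config$max_seq_len
    if (any(over)) {
      warnf("%d sequence(s) longer than max_seq_len (%d); truncating",
            sum(over), config$max_seq_len)
      mats[over] <- lapply(mats[over], function(m)
        m[seq_len(config$max_seq_len), , drop = FALSE])
      lens <- vapply(mats, nrow, 0L)
    }
    null_pos <- lens == 0L
    mats[null_pos] <- list(matrix(0, 1, config$embed_dim))
    lens[null_pos] <- 1L
    stacked <- do.call(rbind, mats)
    sel <- matrix(0, nrow(stacked), 1)
    offs <- cumsum(lens) - lens
    sel[offs[null_pos] + 1L, 1] <- 1
    list(mat = stacked, lens = lens, sel = sel)
  }
  if (F_ > config$max_seq_len)
    stopf("structured sequence (%d slots) exceeds max_seq_len (%d)", F_, config$max_seq_len)
  list(K = K,
       struct = list(mat = name_mat, bins = bins + 1L, lens = rep(F_, K)),
       hist = stack_tokens("history_embeds"),
       diag = stack_tokens("diagnosis_embeds"),
       med = stack_tokens("medication_embeds"))
}

gau_forward <- function(tp, pid, prefix, l, x, lens, config) {
  nm <- function(p) pid[[paste0(prefix, ".", l, ".", p)]]
  nx <- ad_rows_rmsnorm(tp, x, nm("gn"))  # pre-norm residual block
  Z <- ad_silu(tp, ad_add_bias(tp, ad_mm(tp, nx, nm("Wz")), nm("bz")))
  Q <- ad_add_bias(tp, ad_mul_row(tp, Z, nm("gq")), nm("bq"))
  K <- ad_add_bias(tp, ad_mul_row(tp, Z, nm("gk")), nm("bk"))
  U <- ad_silu(tp, ad_add_bias(tp, ad_mm(tp, nx, nm("Wu")), nm("bu")))
  V <- ad_silu(tp, ad_add_bias(tp, ad_mm(tp, nx, nm("Wv")), nm("bv")))
  A <- ad_block_attn(tp, Q, K, V, lens, config$chunk_size)
  O <- ad_add_bias(tp, ad_mm(tp, ad_mul(tp, U, A), nm("Wo")), nm("bo"))
  ad_add(tp, x, O)  # residual
}

encoder_stack <- function(tp, pid, prefix, x, lens, config) {
  for (l in seq_len(config$n_layers))
    x <- gau_forward(tp, pid, prefix, l, x, lens, config)
  x
}

# Full forward pass producing the projected, L2-normalized triple
# (x, m, d) for a stacked batch. `override` optionally supplies tape
# ids for the embedded input surfaces (used by integrated gradients):
# $slots (assembled structured slots), $hist/$diag/$med (token
# embeddings after null substitution, before the learned projection).
encoder_forward <- function(tp, pid, batch, config, override = NULL) {
  token_input <- function(block, null_param) {
    if (!is.null(block$override)) return(block$override)
    raw <- ad_leaf(tp, block$mat)
    sel <- ad_leaf(tp, block$sel)
    ad_add(tp, raw, ad_mm(tp, sel, pid[[null_param]]))
  }
  # structured slots: projected name embedding + learned bin embedding
  slots <- if (!is.null(override$slots)) override$slots else {
    nm <- ad_mm(tp, ad_leaf(tp, batch$struct$mat), pid$Wsn)
    ad_add(tp, nm, ad_embed_rows(tp, pid$bin_table, batch$struct$bins))
  }
  E <- encoder_stack(tp, pid, "psiE", slots, batch$struct$lens, config)

  hblock <- batch$hist; hblock$override <- override$hist
  N_raw <- token_input(hblock, "null_n")
  N <- ad_add_bias(tp, ad_mm(tp, N_raw, pid$Wn), pid$bn)
  fused <- ad_seq_concat(tp, E, batch$struct$lens, N, batch$hist$lens)
  X <- encoder_stack(tp, pid, "fX", fused$id, fused$lens, config)
  Xp <- ad_pool_mean(tp, X, fused$lens)

  dblock <- batch$diag; dblock$override <- override$diag
  D_raw <- token_input(dblock, "null_d")
  D <- encoder_stack(tp, pid, "fD",
                     ad_add_bias(tp, ad_mm(tp, D_raw, pid$Wdin), pid$bdin),
                     batch$diag$lens, config)
  Dp <- ad_pool_mean(tp, D, batch$diag$lens)

  mblock <- batch$med; mblock$override <- override$med
  M_raw <- token_input(mblock, "null_m")
  M <- encoder_stack(tp, pid, "fM",
                     ad_add_bias(tp, ad_mm(tp, M_raw, pid$Wmin), pid$bmin),
                     batch$med$lens, config)
  Mp <- ad_pool_mean(tp, M, batch$med$lens)

  list(
    x = ad_rows_l2norm(tp, ad_add_bias(tp, ad_mm(tp, Xp, pid$Wx), pid$bx)),
    m = ad_rows_l2norm(tp, ad_add_bias(tp, ad_mm(tp, Mp, pid$Wm), pid$bm)),
    d = ad_rows_l2norm(tp, ad_add_bias(tp, ad_mm(tp, Dp, pid$Wd), pid$bd)))
}

push_params <- function(tp, params) lapply(params, function(p) ad_leaf(tp, p))

#' Encode records into representation triples
#'
#' Deterministic (eval-mode) forward pass: returns the L2-normalized
#' projected vectors x (fused patient state), m (medication) and d
#' (diagnosis) for each record.
#'
#' @param encoded_list list of `encoded_inputs` (see
#'   [assemble_record()]).
#' @param params parameter list from [init_dapcp_params()] or a trained
#'   model.
#' @param config the [dapcp_config()] used to shape the parameters.
#' @param schema the `feature_schema` the inputs were assembled with.
#' @return list with matrices `x`, `m`, `d` (rows = records) and
#'   `record_ids`.
#' @export
encode_records <- function(encoded_list, params, config, schema) {
  batch <- build_batch(encoded_list, config, schema)
  tp <- ad_tape()
  pid <- push_params(tp, params)
  out <- encoder_forward(tp, pid, batch, config)
  list(x = ad_value(tp, out$x), m = ad_value(tp, out$m),
       d = ad_value(tp, out$d),
       record_ids = vapply(encoded_list, function(x) x$record_id, ""))
}

#' InfoNCE loss for one query against a key set
#'
#' Temperature-scaled softmax cross-entropy of the query--key dot
#' products with a single positive key:
#' `-log( exp(q.k+ / tau) / sum_i exp(q.k_i / tau) )`.
#'
#' @param q numeric query vector.
#' @param keys matrix of K keys (rows).
#' @param positive_index row index of the positive key.
#' @param tau temperature, > 0.
#' @return loss scalar.
#' @export
info_nce <- function(q, keys, positive_index, tau) {
  if (tau <= 0) stopf("tau must be > 0")
  keys <- as.matrix(keys)
  if (positive_index < 1 || positive_index > nrow(keys))
    stopf("positive_index out of range")
  sims <- as.numeric(keys %*% as.numeric(q)) / tau
  mx <- max(sims)
  -(sims[positive_index] - (mx + log(sum(exp(sims - mx)))))
}

#' Paired contrastive loss over a batch of representation triples
#'
#' The sum of four directed InfoNCE terms,
#' `L(x,m) + L(m,x) + L(x,d) + L(d,x)`, each averaged over batch rows,
#' with row i of each similarity matrix using column i as its positive
#' key.
#'
#' @param x,m,d numeric matrices (batch rows; equal shapes).
#' @param tau temperature, > 0.
#' @return loss scalar. A batch of one row is defined (all terms zero)
#'   but warned about.
#' @export
paired_contrastive_loss <- function(x, m, d, tau) {
  if (tau <= 0) stopf("tau must be > 0")
  x <- as.matrix(x); m <- as.matrix(m); d <- as.matrix(d)
  K <- nrow(x)
  if (K == 1) warnf("contrastive batch of size 1 has no negative keys")
  directed <- function(a, b) mean(vapply(seq_len(K), function(i)
    info_nce(a[i, ], b, i, tau), 0))
  directed(x, m) + directed(m, x) + directed(x, d) + directed(d, x)
}

# global-norm gradient clipping: rescales all gradients together when
# their joint L2 norm exceeds max_norm, stabilizing training under
# conflicting (e.g. label-noise) gradients
clip_grads <- function(grads, max_norm = 5) {
  tot <- sqrt(sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g^2), 0)))
  if (is.finite(tot) && tot > max_norm)
    grads <- lapply(grads, function(g) if (is.null(g)) g else g * (max_norm / tot))
  grads
}

adam_state <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0)) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g) || nm %in% skip) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# gradients of the paired contrastive loss for one batch; returns
# list(loss, retrieval, grads-by-param-name)
lcp_batch_pass <- function(encoded_batch, params, config, schema,
                           compute_grads = TRUE) {
  batch <- build_batch(encoded_batch, config, schema)
  tp <- ad_tape()
  pid <- push_params(tp, params)
  out <- encoder_forward(tp, pid, batch, config)
  tau <- config$temperature
  Sxm <- ad_scale(tp, ad_mm_nt(tp, out$x, out$m), 1 / tau)
  Sxd <- ad_scale(tp, ad_mm_nt(tp, out$x, out$d), 1 / tau)
  loss <- ad_sum_scalars(tp, c(
    ad_info_nce_diag(tp, Sxm), ad_info_nce_diag(tp, ad_t(tp, Sxm)),
    ad_info_nce_diag(tp, Sxd), ad_info_nce_diag(tp, ad_t(tp, Sxd))))
  sim_xd <- ad_value(tp, out$x) %*% t(ad_value(tp, out$d))
  retrieval <- mean(max.col(sim_xd, ties.method = "first") == seq_len(nrow(sim_xd)))
  grads <- NULL
  if (compute_grads) {
    gl <- ad_backward(tp, loss)
    grads <- lapply(pid, function(i) gl[[i]])
  }
  list(loss = as.numeric(ad_value(tp, loss)), retrieval = retrieval,
       grads = grads)
}

#' Contrastive pre-training
#'
#' Mini-batch Adam training of the paired contrastive loss on encoded
#' discharge records. Per-epoch mean loss and in-batch x-to-d retrieval
#' top-1 accuracy (fraction of rows whose most similar diagnosis vector
#' in the batch is their own) are recorded; epoch 0 rows report the
#' randomly initialized model before any update.
#'
#' @param encoded_list list of `encoded_inputs`.
#' @param config a [dapcp_config()].
#' @param schema the `feature_schema` used for assembly.
#' @return object of class `dapcp_model`: `$params`, `$config`,
#'   `$schema`, `$trace` (epoch, mean loss, mean retrieval accuracy).
#' @export
pretrain <- function(encoded_list, config = dapcp_config(), schema) {
  n <- length(encoded_list)
  if (n < 2) stopf("pre-training needs at least 2 records")
  params <- init_dapcp_params(config, schema)
  state <- adam_state(params)
  K <- min(config$batch_size, n)

  eval_pass <- function() {
    idx <- seq_len(n)
    losses <- c(); accs <- c()
    for (b in split(idx, ceiling(seq_along(idx) / K))) {
      if (length(b) < 2) next
      r <- lcp_batch_pass(encoded_list[b], params, config, schema, FALSE)
      losses <- c(losses, r$loss); accs <- c(accs, r$retrieval)
    }
    c(mean(losses), mean(accs))
  }

  ev0 <- eval_pass()
  trace <- data.frame(epoch = 0L, loss = ev0[1], retrieval = ev0[2])
  for (ep in seq_len(config$epochs)) {
    idx <- with_rng(derive_seed(config$seed, paste0("shuffle", ep)), sample.int(n))
    losses <- c(); accs <- c()
    for (b in split(idx, ceiling(seq_along(idx) / K))) {
      if (length(b) < 2) next
      r <- lcp_batch_pass(encoded_list[b], params, config, schema, TRUE)
      if (!is.finite(r$loss))
        stopf("contrastive loss diverged (non-finite) at epoch %d", ep)
      upd <- adam_step(params, clip_grads(r$grads), state, config$lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, r$loss); accs <- c(accs, r$retrieval)
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                     retrieval = mean(accs)))
  }
  structure(list(params = params, config = config, schema = schema,
                 trace = trace),
            class = "dapcp_model")
}

#' Serialize / restore a pre-trained checkpoint
#'
#' JSON container holding the encoder configuration, the feature
#' schema, all weight matrices (full precision) and the training trace.
#'
#' @param model a `dapcp_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly; `read_checkpoint()` returns the model.
#' @export
write_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    schema = unclass(model$schema),
    params = lapply(model$params, function(p)
      list(dim = dim(p), data = as.numeric(p))),
    trace = model$trace)
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = I(17), na = "null")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  config <- structure(p$config, class = "dapcp_config")
  config[c("embed_dim", "proj_dim", "n_layers", "attn_dim", "expansion",
           "chunk_size", "max_seq_len", "batch_size", "epochs", "seed")] <-
    lapply(config[c("embed_dim", "proj_dim", "n_layers", "attn_dim",
                    "expansion", "chunk_size", "max_seq_len", "batch_size",
                    "epochs", "seed")], as.integer)
  schema <- p$schema
  schema$features <- lapply(schema$features, function(f) {
    f$edges <- as.numeric(f$edges)
    if (!is.null(f$levels)) f$levels <- as.character(f$levels)
    f
  })
  schema$n_bins <- as.integer(schema$n_bins)
  schema$embed_dim <- as.integer(schema$embed_dim)
  schema$max_history_len <- as.integer(schema$max_history_len)
  schema$stop_tokens <- as.character(schema$stop_tokens)
  class(schema) <- "feature_schema"
  params <- lapply(p$params, function(q) matrix(q$data, q$dim[1], q$dim[2]))
  structure(list(params = params, config = config, schema = schema,
                 trace = as.data.frame(p$trace)),
            class = "dapcp_model")
}
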