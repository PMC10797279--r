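# Integrated-gradients attribution of fine-tuned predictions. The
# differentiable input surface is the embedded record: the assembled
# structured slot matrix and the three token-embedding blocks. The
# baseline is a "no information" patient: every structured feature in
# the missing bin and every token block replaced by the learned null
# token.

#' Integrated gradients (midpoint rule)
#'
#' `IG_i = (x_i - x'_i) * (1/m) * sum_t dF/dx_i` evaluated at the `m`
#' midpoints of the straight path from the reference input `x'` to the
#' input `x`.
#'
#' @param grad_f function taking an input of the same shape as `x` and
#'   returning the gradient of the scalar model output with respect to
#'   it (same shape). For list inputs, a list of gradients.
#' @param x,x_baseline input and reference input: numeric
#'   vectors/matrices, or lists of them with identical shapes.
#' @param steps number of path steps `m` (>= 2).
#' @return per-dimension scores, same shape as `x`.
#' @export
integrated_gradients <- function(grad_f, x, x_baseline, steps = 50L) {
  if (steps < 2) stopf("steps must be >= 2")
  is_list <- is.list(x)
  check_shape <- function(a, b) {
    if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
      stopf("x and x_baseline shapes differ")
  }
  if (is_list) {
    if (!is.list(x_baseline) || length(x) != length(x_baseline))
      stopf("x and x_baseline shapes differ")
    mapply(check_shape, x, x_baseline)
    delta <- mapply(function(a, b) a - b, x, x_baseline, SIMPLIFY = FALSE)
    acc <- lapply(delta, function(d) d * 0)
    for (t in seq_len(steps)) {
      alpha <- (t - 0.5) / steps
      xt <- mapply(function(b, d) b + alpha * d, x_baseline, delta,
                   SIMPLIFY = FALSE)
      g <- grad_f(xt)
      acc <- mapply(`+`, acc, g, SIMPLIFY = FALSE)
    }
    mapply(function(d, a) d * a / steps, delta, acc, SIMPLIFY = FALSE)
  } else {
    check_shape(x, x_baseline)
    delta <- x - x_baseline
    acc <- delta * 0
    for (t in seq_len(steps)) {
      alpha <- (t - 0.5) / steps
      acc <- acc + grad_f(x_baseline + alpha * delta)
    }
    delta * acc / steps
  }
}

# input surfaces (embedded) for a single record under given params
record_surfaces <- function(params, batch, schema) {
  token_surface <- function(block, null_vec) {
    actual <- block$mat
    null_rows <- block$sel[, 1] == 1
    actual[null_rows, ] <- matrix(rep(null_vec, sum(null_rows)),
                                  ncol = length(null_vec), byrow = TRUE)
    baseline <- matrix(rep(null_vec, nrow(actual)),
                       ncol = length(null_vec), byrow = TRUE)
    list(actual = actual, baseline = baseline)
  }
  name_proj <- batch$struct$mat %*% params$Wsn
  slots <- list(
    actual = name_proj + params$bin_table[batch$struct$bins, , drop = FALSE],
    baseline = name_proj + params$bin_table[rep(nrow(params$bin_table), length(batch$struct$bins)), , drop = FALSE])
  list(slots = slots,
       hist = token_surface(batch$hist, as.numeric(params$null_n)),
       diag = token_surface(batch$diag, as.numeric(params$null_d)),
       med = token_surface(batch$med, as.numeric(params$null_m)))
}

# scalar logit and gradients with respect to the four input surfaces
ig_logit_grad <- function(params, batch, config, inputs) {
  tp <- ad_tape()
  pid <- push_params(tp, params)
  # token overrides enter after null substitution, before the learned
  # input projections; the slot override replaces name+bin embedding
  ids <- list(slots = ad_leaf(tp, inputs$slots),
              hist = ad_leaf(tp, inputs$hist),
              diag = ad_leaf(tp, inputs$diag),
              med = ad_leaf(tp, inputs$med))
  logit <- ft_forward_override(tp, pid, batch, config, ids)
  gl <- ad_backward(tp, logit)
  list(value = as.numeric(ad_value(tp, logit)),
       grads = lapply(ids, function(i) gl[[i]] %||% (ad_value(tp, i) * 0)))
}

ft_forward_override <- function(tp, pid, batch, config, ids) {
  out <- encoder_forward(tp, pid, batch, config,
                         override = list(slots = ids$slots, hist = ids$hist,
                                         diag = ids$diag, med = ids$med))
  rep3 <- ad_cbind(tp, c(out$x, out$m, out$d))
  ad_add_bias(tp, ad_mm(tp, rep3, pid$Wu), pid$bu)
}

#' Integrated-gradients attribution of fine-tuned predictions
#'
#' Attributes each record's predicted logit over the embedded input
#' representation, then sums IG over the embedding dimensions of each
#' input element so every clinical feature (one demographic, one lab,
#' one history token, one diagnosis code, one medication code) gets a
#' single signed score.
#'
#' @param model a `dapft_model`.
#' @param encoded_list records to attribute.
#' @param steps path steps `m` for [integrated_gradients()].
#' @return data.frame with `record_id`, `feature_name`, `type`
#'   (`Demographic`/`Lab`/`History`/`Diagnosis`/`Drug`), `score`;
#'   attribute `completeness` holds per-record
#'   `|sum(IG) - (F(x) - F(x'))|`.
#' @export
attribute_records <- function(model, encoded_list, steps = 50L) {
  params <- model$params
  config <- model$encoder_config
  schema <- model$schema
  rows <- list()
  completeness <- numeric(length(encoded_list))
  for (ri in seq_along(encoded_list)) {
    enc <- encoded_list[[ri]]
    batch <- build_batch(list(enc), config, schema)
    surf <- record_surfaces(params, batch, schema)
    x <- lapply(surf, `[[`, "actual")
    x0 <- lapply(surf, `[[`, "baseline")
    grad_f <- function(inputs) ig_logit_grad(params, batch, config, inputs)$grads
    ig <- integrated_gradients(grad_f, x, x0, steps)
    fx <- ig_logit_grad(params, batch, config, x)$value
    fx0 <- ig_logit_grad(params, batch, config, x0)$value
    completeness[ri] <- abs(sum(vapply(ig, sum, 0)) - (fx - fx0))

    n_demo <- 3L
    feats <- c(schema$feature_names,
               if (length(enc$history_tokens)) enc$history_tokens else "<empty history>",
               if (length(enc$diagnosis_codes)) enc$diagnosis_codes else "<empty diagnosis>",
               if (length(enc$medication_codes)) enc$medication_codes else "<empty medication>")
    types <- c(rep("Demographic", n_demo),
               rep("Lab", length(schema$feature_names) - n_demo),
               rep("History", max(1L, length(enc$history_tokens))),
               rep("Diagnosis", max(1L, length(enc$diagnosis_codes))),
               rep("Drug", max(1L, length(enc$medication_codes))))
    scores <- c(rowSums(ig$slots), rowSums(ig$hist), rowSums(ig$diag),
                rowSums(ig$med))
    rows[[ri]] <- data.frame(record_id = enc$record_id,
                             feature_name = feats, type = types,
                             score = scores, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), completeness = completeness)
}

#' Aggregate per-dimension IG scores and rank the top features
#'
#' Sums the dimensions belonging to each feature, averages across the
#' attributed records, and returns the `k` features with the highest
#' mean score.
#'
#' @param scores numeric matrix (records x dimensions) or vector of
#'   per-dimension IG scores.
#' @param feature_map character vector naming the owning feature of
#'   each dimension; `NA` entries (unmapped dimensions) are an error.
#' @param k number of top features to return.
#' @param types optional character vector of feature types per
#'   dimension.
#' @return data.frame `feature_name`, `type`, `mean_ig`, ranked by
#'   `mean_ig` descending; all features when `k` exceeds the feature
#'   count.
#' @export
aggregate_and_rank <- function(scores, feature_map, k = 20L, types = NULL) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (length(feature_map) != ncol(scores))
    stopf("feature_map length (%d) must equal the dimension count (%d)",
          length(feature_map), ncol(scores))
  if (anyNA(feature_map))
    stopf("unmapped dimension(s): %s",
          paste(which(is.na(feature_map)), collapse = ", "))
  per_feature <- t(rowsum(t(scores), group = feature_map))
  mean_ig <- colMeans(per_feature)
  tmap <- if (!is.null(types)) tapply(types, feature_map, function(x) x[[1]])
  out <- data.frame(feature_name = names(mean_ig),
                    type = if (is.null(tmap)) NA_character_ else
                      as.character(tmap[names(mean_ig)]),
                    mean_ig = as.numeric(mean_ig),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_ig), ]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Top-k attribution table for a fine-tuned model
#'
#' Convenience wrapper: attributes the records, averages per-feature
#' scores across records and returns the ranked table.
#'
#' @inheritParams attribute_records
#' @param k number of features to report.
#' @return data.frame `feature_name`, `type`, `mean_ig`.
#' @export
top_features <- function(model, encoded_list, k = 20L, steps = 50L) {
  att <- attribute_records(model, encoded_list, steps)
  agg <- stats::aggregate(score ~ feature_name + type, data = att, FUN = mean)
  names(agg)[names(agg) == "score"] <- "mean_ig"
  agg <- agg[order(-agg$mean_ig), c("feature_name", "type", "mean_ig")]
  rownames(agg) <- NULL
  utils::head(agg, k)
}
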