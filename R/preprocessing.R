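# Preprocessing: isolation-forest outlier screening of numeric labs,
# quantile discretization with a reserved missing bin, deterministic
# static embeddings for token/text fields, and assembly of one
# discharge record into model-ready encoded inputs.

harmonic <- function(m) if (m < 1) 0 else log(m) + 0.5772156649015329

# average unsuccessful-search path length in a BST of n points
avg_path_len <- function(n) {
  ifelse(n <= 1, 0, ifelse(n == 2, 1, 2 * harmonic(n - 1) - 2 * (n - 1) / n))
}

build_itree <- function(x, idx, height, limit) {
  n <- length(idx)
  if (n <= 1 || height >= limit) {
    return(list(leaf = TRUE, size = n))
  }
  # candidate features with spread at this node
  spread <- apply(x[idx, , drop = FALSE], 2, function(v) diff(range(v)))
  ok <- which(spread > 0)
  if (!length(ok)) return(list(leaf = TRUE, size = n))
  f <- if (length(ok) == 1) ok else sample(ok, 1)
  rng <- range(x[idx, f])
  split <- stats::runif(1, rng[1], rng[2])
  left <- idx[x[idx, f] < split]
  right <- idx[x[idx, f] >= split]
  if (!length(left) || !length(right)) return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, feature = f, split = split,
       left = build_itree(x, left, height + 1, limit),
       right = build_itree(x, right, height + 1, limit))
}

itree_depths <- function(tree, x, idx, depth, out) {
  if (tree$leaf) {
    out[idx] <- depth + avg_path_len(tree$size)
    return(out)
  }
  go_left <- x[idx, tree$feature] < tree$split
  if (any(go_left)) out <- itree_depths(tree$left, x, idx[go_left], depth + 1, out)
  if (any(!go_left)) out <- itree_depths(tree$right, x, idx[!go_left], depth + 1, out)
  out
}

#' Isolation-forest outlier detection
#'
#' Flags anomalous rows of a numeric matrix with an isolation-forest
#' ensemble: trees of random axis-aligned splits, anomaly score
#' `2^(-E[h]/c(psi))` from the mean path length `E[h]` over trees.
#' Missing cells are median-imputed internally for scoring only.
#'
#' @param values numeric matrix with at least 16 rows.
#' @param contamination expected outlier fraction, in (0, 0.5); the
#'   `round(contamination * nrow)` highest-scoring rows (at least 1) are
#'   flagged.
#' @param seed integer seed; identical input and seed give an identical
#'   mask.
#' @param n_trees,sample_size ensemble size and per-tree subsample.
#' @return logical vector of length `nrow(values)`; `TRUE` = outlier.
#'   An all-constant matrix yields no flags, with a warning.
#' @export
detect_outliers <- function(values, contamination = 0.05, seed = 1L,
                            n_trees = 100L, sample_size = 256L) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 16) stopf("detect_outliers needs >= 16 rows, got %d", n)
  if (contamination <= 0 || contamination >= 0.5)
    stopf("contamination must lie in (0, 0.5)")
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    if (anyNA(v)) values[is.na(v), j] <- stats::median(v, na.rm = TRUE)
  }
  if (all(apply(values, 2, function(v) diff(range(v)) == 0))) {
    warnf("all-constant matrix: no outliers flagged")
    return(rep(FALSE, n))
  }
  psi <- min(sample_size, n)
  limit <- ceiling(log2(psi))
  scores <- with_rng(seed, {
    depth_sum <- numeric(n)
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      tree <- build_itree(values, idx, 0, limit)
      depth_sum <- depth_sum + itree_depths(tree, values, seq_len(n), 0, numeric(n))
    }
    2^(-(depth_sum / n_trees) / avg_path_len(psi))
  })
  k <- max(1L, round(contamination * n))
  mask <- rep(FALSE, n)
  mask[order(scores, decreasing = TRUE)[seq_len(k)]] <- TRUE
  mask
}

#' Mask the labs of outlying records
#'
#' Runs [detect_outliers()] on the lab matrix of a record list and sets
#' the labs of flagged records to missing (cell masking preserves the
#' sample for all other fields).
#'
#' @param records list of `discharge_record`.
#' @param contamination,seed passed to [detect_outliers()].
#' @return the record list with flagged records' labs set to `NA`, with
#'   attribute `outlier_mask`.
#' @export
screen_lab_outliers <- function(records, contamination = 0.02, seed = 1L) {
  labm <- lab_matrix(records)
  if (nrow(labm) < 16) return(structure(records, outlier_mask = rep(FALSE, length(records))))
  mask <- detect_outliers(labm, contamination = contamination, seed = seed)
  for (i in which(mask)) records[[i]]$labs[] <- NA_real_
  structure(records, outlier_mask = mask)
}

# records -> numeric matrix (rows = records, cols = union of lab names)
lab_matrix <- function(records) {
  nm <- unique(unlist(lapply(records, function(r) names(r$labs))))
  m <- matrix(NA_real_, length(records), length(nm), dimnames = list(NULL, nm))
  for (i in seq_along(records)) {
    labs <- records[[i]]$labs
    if (length(labs)) m[i, names(labs)] <- as.numeric(labs)
  }
  m
}

#' Fit quantile bin edges for numeric features
#'
#' Interior edges at empirical quantiles of the training values; values
#' outside the fitted range clamp into the first/last bin; missing maps
#' to a reserved bin with index `n_bins`.
#'
#' @param train_values named list of numeric vectors (one per feature),
#'   training split only.
#' @param n_bins number of bins, at least 2.
#' @return named list of strictly increasing interior edge vectors (a
#'   constant feature gets no interior edges: a single effective bin).
#' @export
fit_discretizer <- function(train_values, n_bins = 10L) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  lapply(train_values, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(numeric(0))
    e <- unique(stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins,
                                names = FALSE, type = 7))
    e <- e[diff(c(-Inf, e)) > 0]
    # an edge at the minimum would leave bin 0 empty (and make a
    # constant feature span two bins); drop it
    e[e > min(v)]
  })
}

#' Discretize a value against a fitted schema
#'
#' @param value numeric scalar (or vector), `NA` allowed.
#' @param feature feature name present in the schema.
#' @param schema a `feature_schema` from [fit_schema()].
#' @return 0-based bin index; `NA` values map to the reserved missing
#'   bin (`schema$n_bins`).
#' @export
discretize <- function(value, feature, schema) {
  ft <- schema$features[[feature]]
  if (is.null(ft)) stopf("feature '%s' absent from schema", feature)
  if (ft$type == "numeric") {
    idx <- findInterval(value, ft$edges)
    idx[is.na(value)] <- schema$n_bins
    idx
  } else {
    idx <- match(as.character(value), ft$levels) - 1L
    idx[is.na(idx)] <- schema$n_bins
    idx
  }
}

#' Fit the feature schema on training records
#'
#' Derives, from the training split only, the per-feature discretization
#' (quantile bin edges for age and labs; level tables for sex and
#' marital status), the embedding dimension and the history-token
#' policy. The schema is the single source of truth for
#' [assemble_record()].
#'
#' @param records training-split `discharge_record` list.
#' @param n_bins bins per numeric feature (default deciles).
#' @param embed_dim static embedding dimension.
#' @param max_history_len history-token truncation length.
#' @param stop_tokens non-informative tokens dropped from histories
#'   before embedding.
#' @return object of class `feature_schema`.
#' @export
fit_schema <- function(records, n_bins = 10L, embed_dim = 32L,
                       max_history_len = 32L, stop_tokens = character(0)) {
  labm <- lab_matrix(records)
  ages <- vapply(records, function(r) r$age, 0)
  num_edges <- fit_discretizer(
    c(list(age = ages), as.list(as.data.frame(labm))), n_bins = n_bins)
  features <- list(
    age = list(type = "numeric", edges = num_edges$age),
    sex = list(type = "categorical", levels = c("F", "M")),
    marital_status = list(
      type = "categorical",
      levels = sort(unique(vapply(records, function(r) r$marital_status, ""))))
  )
  for (nm in colnames(labm))
    features[[nm]] <- list(type = "numeric", edges = num_edges[[nm]])
  structure(list(
    features = features,
    feature_names = names(features),
    lab_names = colnames(labm),
    n_bins = as.integer(n_bins),
    embed_dim = as.integer(embed_dim),
    max_history_len = as.integer(max_history_len),
    stop_tokens = stop_tokens
  ), class = "feature_schema")
}

#' Serialize / restore a feature schema
#' @param schema a `feature_schema`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_schema()` returns the schema.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s$features <- lapply(s$features, function(f) {
    f$edges <- as.numeric(f$edges)
    if (!is.null(f$levels)) f$levels <- as.character(f$levels)
    f
  })
  s$n_bins <- as.integer(s$n_bins)
  s$embed_dim <- as.integer(s$embed_dim)
  s$max_history_len <- as.integer(s$max_history_len)
  s$stop_tokens <- as.character(s$stop_tokens)
  structure(s, class = "feature_schema")
}

# process-wide cache of static embeddings
.embed_cache <- new.env(parent = emptyenv())

#' Deterministic static token embedding
#'
#' Stands in for a large-language-model static encoder as a
#' pre-processing step: each token maps to a fixed pseudo-random
#' unit-norm vector obtained by hashing the token string to an RNG seed.
#' Identical tokens give identical vectors across runs and machines; the
#' caller's RNG stream is untouched.
#'
#' @param tokens character vector (possibly empty).
#' @param dim embedding dimension, positive.
#' @return `length(tokens) x dim` numeric matrix (0 rows when empty).
#' @export
embed_static <- function(tokens, dim) {
  if (dim < 1) stopf("dim must be positive")
  out <- matrix(0, length(tokens), dim)
  for (i in seq_along(tokens)) {
    key <- paste0(dim, "#", tokens[[i]])
    v <- .embed_cache[[key]]
    if (is.null(v)) {
      v <- with_rng(fnv1a_hash(key), stats::rnorm(dim))
      v <- v / sqrt(sum(v^2))
      .embed_cache[[key]] <- v
    }
    out[i, ] <- v
  }
  out
}

#' Assemble one discharge record into encoded model inputs
#'
#' Produces the four input blocks consumed by the encoder:
#' * `E` (structured): per demographic/lab feature, the static
#'   feature-name embedding plus a 0-based bin index (missing bin for
#'   `NA`), in the fixed order age, sex, marital status, then labs in
#'   schema order;
#' * `N` (history): stop-token-filtered, truncated history-token
#'   embeddings;
#' * `D_text` / `M_text`: diagnosis-name and medication-name embeddings.
#'
#' Empty token blocks are flagged so the fusion stage can substitute its
#' learned null token.
#'
#' @param record a `discharge_record`.
#' @param schema a fitted `feature_schema`.
#' @return object of class `encoded_inputs`.
#' @export
assemble_record <- function(record, schema) {
  unknown <- setdiff(names(record$labs), schema$lab_names)
  if (length(unknown))
    stopf("record %s references lab(s) unknown to the schema: %s",
          record$record_id, paste(unknown, collapse = ", "))
  dim <- schema$embed_dim
  fn <- schema$feature_names
  vals <- c(list(record$age, record$sex, record$marital_status),
            lapply(schema$lab_names, function(nm) {
              v <- record$labs[[nm]]
              if (is.null(v)) NA_real_ else v
            }))
  bins <- vapply(seq_along(fn), function(i)
    as.integer(discretize(vals[[i]], fn[[i]], schema)), 0L)
  hx <- record$history_tokens[!record$history_tokens %in% schema$stop_tokens]
  hx <- utils::head(hx, schema$max_history_len)
  structure(list(
    record_id = record$record_id,
    patient_id = record$patient_id,
    feature_names = fn,
    name_embeds = embed_static(fn, dim),
    bins = bins,
    history_tokens = hx,
    history_embeds = embed_static(hx, dim),
    diagnosis_codes = record$diagnosis_codes,
    diagnosis_embeds = embed_static(record$diagnosis_codes, dim),
    medication_codes = record$medication_codes,
    medication_embeds = embed_static(record$medication_codes, dim)
  ), class = "encoded_inputs")
}

#' Assemble a list of records
#' @param records list of `discharge_record`.
#' @param schema a fitted `feature_schema`.
#' @return list of `encoded_inputs`.
#' @export
assemble_records <- function(records, schema)
  lapply(records, assemble_record, schema = schema)
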