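# Minimal tape-based reverse-mode automatic differentiation over
# matrices. Every value on the tape is a numeric matrix (scalars are
# 1x1). Operations append nodes in topological order; ad_backward()
# walks the tape once in reverse, so gradients for all leaves (model
# parameters or embedded inputs) come from a single pass.
#
# Sequence batches are held in "stacked" form: the sequences of all
# records in a batch are row-concatenated into one matrix together with
# a vector of per-record lengths. Position-wise operations then cost
# one matrix op per batch, and only the attention/pooling nodes loop
# over records.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- list()
  tp$parents <- list()
  tp$backs <- list()
  tp
}

ad_push <- function(tp, val, parents = integer(0), back = NULL) {
  i <- tp$n + 1L
  tp$n <- i
  tp$vals[[i]] <- val
  tp$parents[[i]] <- parents
  tp$backs[[i]] <- back
  i
}

ad_leaf <- function(tp, x) ad_push(tp, as.matrix(x))

ad_value <- function(tp, id) { force(id); tp$vals[[id]] }

# Backward pass from a scalar root. Returns the list of gradients by
# node id (NULL where no gradient flows).
ad_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root]] <- matrix(1, 1, 1)
  for (i in seq(root, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$backs[[i]])) next
    pg <- tp$backs[[i]](g)
    ps <- tp$parents[[i]]
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

## ---- elementary ops ----

ad_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A %*% B, c(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

# A %*% t(B)
ad_mm_nt <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A %*% t(B), c(a, b),
          function(g) list(g %*% B, t(g) %*% A))
}

ad_t <- function(tp, a) {
  force(a)
  ad_push(tp, t(tp$vals[[a]]), a, function(g) list(t(g)))
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

# A (n x d) + bias row b (1 x d), broadcast over rows
ad_add_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; bv <- tp$vals[[b]]
  ad_push(tp, sweep(A, 2, as.numeric(bv), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

ad_scale <- function(tp, a, s) {
  force(a)
  ad_push(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# A (n x d) * row vector r (1 x d), broadcast over rows
ad_mul_row <- function(tp, a, r) {
  force(a); force(r)
  A <- tp$vals[[a]]; rv <- as.numeric(tp$vals[[r]])
  ad_push(tp, sweep(A, 2, rv, "*"), c(a, r),
          function(g) list(sweep(g, 2, rv, "*"),
                           matrix(colSums(g * A), 1)))
}

ad_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  ad_push(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  S <- 1 / (1 + exp(-tp$vals[[a]]))
  ad_push(tp, S, a, function(g) list(g * S * (1 - S)))
}

# SiLU / swish activation x * sigmoid(x)
ad_silu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  S <- 1 / (1 + exp(-A))
  ad_push(tp, A * S, a, function(g) list(g * (S * (1 + A * (1 - S)))))
}

# rows of table (param) selected by integer idx (1-based); gradient
# accumulates by row via rowsum
ad_embed_rows <- function(tp, table, idx) {
  force(table)
  Tm <- tp$vals[[table]]
  ad_push(tp, Tm[idx, , drop = FALSE], table, function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nrow(Tm), ncol(Tm))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# row-wise RMS normalization with a learned per-dimension gain (1 x d):
# y = gain * x / sqrt(mean(x^2) + eps). Pre-norm placement keeps deep
# residual stacks bounded.
ad_rows_rmsnorm <- function(tp, a, gain, eps = 1e-8) {
  force(a); force(gain)
  A <- tp$vals[[a]]
  gv <- as.numeric(tp$vals[[gain]])
  d <- ncol(A)
  r <- sqrt(rowMeans(A^2) + eps)
  Y <- sweep(A / r, 2, gv, "*")
  ad_push(tp, Y, c(a, gain), function(g) {
    gg <- sweep(g, 2, gv, "*")          # dL/d(x/r)
    dot <- rowSums(gg * A)
    dA <- gg / r - A * (dot / (d * r^3))
    dgain <- matrix(colSums(g * (A / r)), 1)
    list(dA, dgain)
  })
}

# L2-normalize each row
ad_rows_l2norm <- function(tp, a, eps = 1e-12) {
  force(a)
  A <- tp$vals[[a]]
  nrm <- sqrt(rowSums(A^2)) + eps
  Y <- A / nrm
  ad_push(tp, Y, a, function(g) {
    dot <- rowSums(g * A)
    list(g / nrm - A * (dot / nrm^3))
  })
}

# mean over each record's rows of a stacked sequence matrix
ad_pool_mean <- function(tp, a, lens) {
  force(a)
  A <- tp$vals[[a]]
  grp <- rep(seq_along(lens), lens)
  M <- rowsum(A, grp) / lens
  dimnames(M) <- NULL
  ad_push(tp, M, a, function(g) {
    list(g[grp, , drop = FALSE] / lens[grp])
  })
}

# concatenate two stacked sequence sets record-by-record; returns id and
# the combined lengths
ad_seq_concat <- function(tp, a, lens_a, b, lens_b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  stopifnot(length(lens_a) == length(lens_b))
  off_a <- cumsum(lens_a) - lens_a
  off_b <- cumsum(lens_b) - lens_b
  idx_a <- unlist(lapply(seq_along(lens_a), function(i)
    seq_len(lens_a[i]) + off_a[i]), use.names = FALSE)
  # interleave: positions of A rows and B rows in the output
  pos <- unlist(lapply(seq_along(lens_a), function(i)
    c(rep(1L, lens_a[i]), rep(2L, lens_b[i]))), use.names = FALSE)
  out <- matrix(0, nrow(A) + nrow(B), ncol(A))
  out[pos == 1L, ] <- A
  out[pos == 2L, ] <- B
  id <- ad_push(tp, out, c(a, b), function(g)
    list(g[pos == 1L, , drop = FALSE], g[pos == 2L, , drop = FALSE]))
  list(id = id, lens = lens_a + lens_b)
}

# column-concatenate matrices with equal row counts
ad_cbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  ncols <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_push(tp, do.call(cbind, vals), as.integer(ids), function(g)
    lapply(seq_along(ids), function(j) g[, starts[j]:ends[j], drop = FALSE]))
}

## ---- gated attention (FLASH-style) mixing ----

# Blockwise gated attention over stacked sequences: for each record,
# quadratic squared-ReLU attention within chunks of `chunk` positions
# plus a global linear-attention term, per the single-head gated linear
# attention design. q, k: stacked (sum S_i) x e; v: stacked x h.
ad_block_attn <- function(tp, q, k, v, lens, chunk) {
  force(q); force(k); force(v)
  Q <- tp$vals[[q]]; K <- tp$vals[[k]]; V <- tp$vals[[v]]
  e <- ncol(Q)
  offs <- cumsum(lens) - lens
  O <- matrix(0, nrow(V), ncol(V))
  cache <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    S <- lens[i]
    rows <- offs[i] + seq_len(S)
    Qi <- Q[rows, , drop = FALSE]; Ki <- K[rows, , drop = FALSE]
    Vi <- V[rows, , drop = FALSE]
    G <- crossprod(Ki, Vi)                      # e x h, global linear term
    Oi <- (Qi %*% G) / S
    ch <- split(seq_len(S), ceiling(seq_len(S) / chunk))
    Ps <- vector("list", length(ch))
    for (ci in seq_along(ch)) {
      cc <- ch[[ci]]
      P <- pmax(Qi[cc, , drop = FALSE] %*% t(Ki[cc, , drop = FALSE]) / sqrt(e), 0)
      Ps[[ci]] <- P
      Oi[cc, ] <- Oi[cc, ] + (P^2 %*% Vi[cc, , drop = FALSE]) / S
    }
    O[rows, ] <- Oi
    cache[[i]] <- list(rows = rows, G = G, ch = ch, Ps = Ps)
  }
  ad_push(tp, O, c(q, k, v), function(g) {
    dQ <- matrix(0, nrow(Q), e); dK <- matrix(0, nrow(K), e)
    dV <- matrix(0, nrow(V), ncol(V))
    for (i in seq_along(lens)) {
      S <- lens[i]
      cc0 <- cache[[i]]
      rows <- cc0$rows
      Qi <- Q[rows, , drop = FALSE]; Ki <- K[rows, , drop = FALSE]
      Vi <- V[rows, , drop = FALSE]
      Gi <- g[rows, , drop = FALSE]
      # linear term: O = Qi G / S with G = Ki' Vi
      dQ[rows, ] <- dQ[rows, ] + (Gi %*% t(cc0$G)) / S
      dG <- crossprod(Qi, Gi) / S
      dK[rows, ] <- dK[rows, ] + Vi %*% t(dG)
      dV[rows, ] <- dV[rows, ] + Ki %*% dG
      # quadratic chunks: O_cc += relu(Q K'/sqrt(e))^2 V / S
      for (ci in seq_along(cc0$ch)) {
        cc <- cc0$ch[[ci]]
        P <- cc0$Ps[[ci]]
        Gcc <- Gi[cc, , drop = FALSE]
        Vcc <- Vi[cc, , drop = FALSE]
        dV[rows[cc], ] <- dV[rows[cc], ] + crossprod(P^2, Gcc) / S
        dA <- Gcc %*% t(Vcc) / S          # grad wrt P^2
        dP <- 2 * P * dA                  # relu already folded into P >= 0
        dQ[rows[cc], ] <- dQ[rows[cc], ] + (dP %*% Ki[cc, , drop = FALSE]) / sqrt(e)
        dK[rows[cc], ] <- dK[rows[cc], ] + (crossprod(dP, Qi[cc, , drop = FALSE])) / sqrt(e)
      }
    }
    list(dQ, dK, dV)
  })
}

## ---- losses ----

# mean over rows of -log softmax at the diagonal of a K x K similarity
# matrix (InfoNCE with positives on the diagonal)
ad_info_nce_diag <- function(tp, s) {
  force(s)
  S <- tp$vals[[s]]
  K <- nrow(S)
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  loss <- mean(lse - diag(S))
  P <- softmax_rows(S)
  ad_push(tp, matrix(loss, 1, 1), s, function(g)
    list(as.numeric(g) * (P - diag(K)) / K))
}

# mean binary cross-entropy of logits against labels y in {0,1}
ad_bce_logits <- function(tp, a, y) {
  force(a)
  L <- as.numeric(tp$vals[[a]])
  n <- length(L)
  # stable: log(1+exp(-|l|)) + max(l,0) - l*y
  loss <- mean(pmax(L, 0) - L * y + log1p(exp(-abs(L))))
  p <- 1 / (1 + exp(-L))
  ad_push(tp, matrix(loss, 1, 1), a, function(g)
    list(matrix(as.numeric(g) * (p - y) / n, nrow(tp$vals[[a]]), ncol(tp$vals[[a]]))))
}

ad_sum_scalars <- function(tp, ids) {
  v <- sum(vapply(ids, function(i) as.numeric(tp$vals[[i]]), 0))
  ad_push(tp, matrix(v, 1, 1), as.integer(ids),
          function(g) rep(list(g), length(ids)))
}
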