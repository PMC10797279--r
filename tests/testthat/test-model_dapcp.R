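test_that("info_nce matches its closed forms", {
  expect_equal(info_nce(c(1, 0), matrix(c(1, 0), 1), 1, tau = 1), 0)

  # query orthogonal to every key: uniform softmax, loss log K
  keys <- diag(4)[, 1:4]
  q <- c(0, 0, 0, 0)
  expect_equal(info_nce(q, keys, 2, tau = 0.3), log(4))

  # two keys, q aligned with the positive
  expect_equal(info_nce(c(1, 0), rbind(c(1, 0), c(0, 1)), 1, tau = 1),
               log(1 + exp(-1)), tolerance = 1e-12)

  expect_error(info_nce(c(1, 0), diag(2), 1, tau = 0), "tau")
  expect_error(info_nce(c(1, 0), diag(2), 3, tau = 1), "positive_index")
})

test_that("paired loss equals its closed forms and the brute-force oracle", {
  # identical triples duplicated: all keys indistinguishable, 4 log B
  B <- 5
  v <- matrix(rep(c(1, 0, 0), B), B, 3, byrow = TRUE)
  expect_equal(paired_contrastive_loss(v, v, v, tau = 1), 4 * log(B))

  # mutually orthogonal rows with x = m = d: each directed term is the
  # equiangular closed form -log(e / (e + B - 1)) at tau = 1
  Bo <- 4
  xo <- diag(Bo)
  expect_equal(paired_contrastive_loss(xo, xo, xo, tau = 1),
               4 * -log(exp(1) / (exp(1) + (Bo - 1))), tolerance = 1e-12)

  set.seed(5)
  x <- rand_unit_rows(3, 8); m <- rand_unit_rows(3, 8); d <- rand_unit_rows(3, 8)
  expect_equal(paired_contrastive_loss(x, m, d, tau = 0.07),
               oracle_paired_loss(x, m, d, tau = 0.07), tolerance = 1e-6)

  expect_warning(paired_contrastive_loss(x[1, , drop = FALSE],
                                         m[1, , drop = FALSE],
                                         d[1, , drop = FALSE], tau = 1),
                 "size 1")
})

test_that("the tape loss equals the reference implementation on real encodings", {
  w <- small_world()
  cfg <- tiny_model_config()
  params <- init_dapcp_params(cfg, w$schema)
  enc <- w$encoded[1:6]
  pass <- dapehr:::lcp_batch_pass(enc, params, cfg, w$schema, FALSE)
  rep_ <- encode_records(enc, params, cfg, w$schema)
  expect_equal(pass$loss,
               paired_contrastive_loss(rep_$x, rep_$m, rep_$d, cfg$temperature),
               tolerance = 1e-10)
})

test_that("encoding is deterministic, normalized, and order-invariant in codes", {
  w <- small_world()
  cfg <- tiny_model_config()
  params <- init_dapcp_params(cfg, w$schema)
  enc <- w$encoded[1:4]
  r1 <- encode_records(enc, params, cfg, w$schema)
  r2 <- encode_records(enc, params, cfg, w$schema)
  expect_identical(r1, r2)
  for (mat in list(r1$x, r1$m, r1$d))
    expect_equal(rowSums(mat^2), rep(1, 4), tolerance = 1e-5)

  # permuting diagnosis codes leaves d unchanged (order-invariant pooling)
  rec <- w$records[[which(vapply(w$records, function(r)
    length(r$diagnosis_codes), 0L) >= 3)[1]]]
  perm <- rec
  perm$diagnosis_codes <- rev(perm$diagnosis_codes)
  e1 <- assemble_record(rec, w$schema)
  e2 <- assemble_record(perm, w$schema)
  d1 <- encode_records(list(e1), params, cfg, w$schema)$d
  d2 <- encode_records(list(e2), params, cfg, w$schema)$d
  expect_lt(max(abs(d1 - d2)), 1e-5)
})

test_that("the loss is invariant to a common rotation of the projections", {
  set.seed(9)
  x <- rand_unit_rows(6, 8); m <- rand_unit_rows(6, 8); d <- rand_unit_rows(6, 8)
  Q <- qr.Q(qr(matrix(stats::rnorm(64), 8, 8)))
  expect_equal(paired_contrastive_loss(x, m, d, 0.1),
               paired_contrastive_loss(x %*% Q, m %*% Q, d %*% Q, 0.1),
               tolerance = 1e-10)
})

test_that("random-init loss approximates 4 log K at moderate temperature", {
  w <- small_world()
  cfg <- tiny_model_config(seed = 77)
  cfg$temperature <- 1
  cfg$batch_size <- 8L
  cfg$epochs <- 0L
  params <- init_dapcp_params(cfg, w$schema)
  losses <- vapply(split(1:40, rep(1:5, each = 8)), function(b)
    dapehr:::lcp_batch_pass(w$encoded[b], params, cfg, w$schema, FALSE)$loss, 0)
  expect_lt(abs(mean(losses) - 4 * log(8)) / (4 * log(8)), 0.10)
})

test_that("checkpoints round-trip through JSON", {
  w <- small_world()
  cfg <- tiny_model_config()
  cfg$epochs <- 1L
  ck <- pretrain(w$encoded[1:24], cfg, w$schema)
  f <- withr::local_tempfile()
  write_checkpoint(ck, f)
  back <- read_checkpoint(f)
  expect_equal(back$params, ck$params, tolerance = 1e-15)
  expect_equal(back$trace, ck$trace, tolerance = 1e-12)
  r1 <- encode_records(w$encoded[1:3], ck$params, ck$config, ck$schema)
  r2 <- encode_records(w$encoded[1:3], back$params, back$config, back$schema)
  expect_equal(r1, r2, tolerance = 1e-12)
})
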