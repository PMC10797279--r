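test_that("ROC-AUC matches closed forms and the pair-counting oracle", {
  expect_equal(auc_roc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(auc_roc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc_roc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  expect_error(auc_roc(c(1, 1), c(0.2, 0.3)), "both classes")

  pair_oracle <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # induce ties
    expect_equal(auc_roc(y, s), pair_oracle(y, s))
  }
})

test_that("ROC-AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- c(0, 1, rbinom(98, 1, 0.3)); s <- rnorm(100)
  expect_equal(auc_roc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("PR-AUC matches closed forms and average precision on tie-free data", {
  expect_equal(auc_pr(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2)), 1)
  expect_equal(auc_pr(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)  # prevalence
  # average-precision oracle: precision at each positive's rank
  ap_oracle <- function(y, s) {
    ord <- order(s, decreasing = TRUE)
    y <- y[ord]
    ranks <- which(y == 1)
    mean(vapply(seq_along(ranks), function(i) i / ranks[i], 0))
  }
  set.seed(12)
  for (i in 1:20) {
    n <- sample(6:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3))
    s <- rnorm(n)  # continuous, no ties
    expect_equal(auc_pr(y, s), ap_oracle(y, s), tolerance = 1e-12)
  }
  expect_error(auc_pr(c(0, 0), c(0.1, 0.2)), "both classes")
})

test_that("fold comparison behaves like a two-sided t-test", {
  expect_equal(compare_folds(rep(0.8, 10), rep(0.8, 10)), 1)
  expect_equal(compare_folds(rep(0.8, 10), rep(0.7, 10)), 0)
  set.seed(2)
  a <- 0.9 + rnorm(10, sd = 0.01)
  b <- 0.5 + rnorm(10, sd = 0.01)
  expect_lt(compare_folds(a, b), 0.001)
  expect_equal(compare_folds(a, b), compare_folds(b, a))
  expect_equal(compare_folds(a, b),
               stats::t.test(a, b)$p.value, tolerance = 1e-12)
  expect_error(compare_folds(a, b[1:5]), "equal length")
})

test_that("net benefit matches its closed forms", {
  # hand-counted example: t = 0.5, TP = 2, FP = 1, n = 8
  y <- c(1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(.9, .6, .55, .4, .3, .2, .1, .05)
  dc <- decision_curve(y, s, thresholds = 0.5)
  expect_equal(dc$net_benefit[dc$curve == "model"], 0.125)

  # perfect classifier at prevalence 1/4: NB = prevalence at every
  # threshold below every positive's score (and above every negative's)
  yp <- c(1, 0, 0, 0); sp <- c(1, 0, 0, 0)
  grid <- seq(0.05, 0.85, by = 0.1)
  dcp <- decision_curve(yp, sp, thresholds = grid)
  expect_equal(dcp$net_benefit[dcp$curve == "model"], rep(0.25, length(grid)))

  # treat-all identity pi - (1 - pi) t / (1 - t), zero at t = pi = 0.25
  ta <- dcp[dcp$curve == "treat_all", ]
  expect_equal(ta$net_benefit, 0.25 - 0.75 * grid / (1 - grid),
               tolerance = 1e-12)
  dc25 <- decision_curve(yp, sp, thresholds = 0.25)
  expect_equal(dc25$net_benefit[dc25$curve == "treat_all"], 0, tolerance = 1e-12)

  expect_true(all(dcp$net_benefit[dcp$curve == "treat_none"] == 0))
  expect_error(decision_curve(y, s, thresholds = c(0.5, 1)), "inside")

  # bound: no model exceeds prevalence at any threshold
  set.seed(6)
  yr <- rbinom(200, 1, 0.3); sr <- runif(200)
  dcr <- decision_curve(yr, sr)
  expect_true(all(dcr$net_benefit[dcr$curve == "model"] <= mean(yr) + 1e-12))
})

test_that("fold assignment is patient-disjoint and stratified", {
  set.seed(31)
  pids <- rep(sprintf("p%03d", 1:80), each = 2)
  labels <- rep(rbinom(80, 1, 0.3), each = 2)
  labels[1:2] <- 1
  folds <- make_patient_folds(pids, labels, k = 5, seed = 3)
  expect_true(all(tapply(folds, pids, function(f) length(unique(f))) == 1))
  expect_true(all(table(folds, labels) > 0))
})

test_that("k-fold evaluation: perfect separation scores 1, permuted labels ~0.5", {
  set.seed(41)
  mk <- function(i, y) discharge_record(
    sprintf("R%03d", i), sprintf("P%03d", i), 0, 2, 60, "F",
    labs = c(sig = y * 10 + rnorm(1, sd = 0.01), noise = rnorm(1)))
  y <- rep(c(0, 1), 30)
  recs <- lapply(seq_along(y), function(i) mk(i, y[i]))
  ev <- kfold_evaluate(recs, y, models = "logistic", k = 5, seed = 2)
  expect_true(all(ev$folds$roc_auc == 1))
  expect_true(all(ev$folds$pr_auc == 1))

  yperm <- sample(y)
  recs_n <- lapply(seq_along(y), function(i) mk(i, 0))  # labs pure noise
  evn <- kfold_evaluate(recs_n, yperm, models = "logistic", k = 5, seed = 2)
  expect_lt(abs(mean(evn$folds$roc_auc) - 0.5), 0.1)
})

test_that("external validation keeps the test cohort fixed across folds", {
  set.seed(51)
  mk <- function(i, y, pid) discharge_record(
    sprintf("X%03d", i), pid, 0, 2, 60, "M",
    labs = c(sig = y * 3 + rnorm(1), noise = rnorm(1)))
  ytr <- rep(c(0, 1), 40)
  tr <- lapply(seq_along(ytr), function(i) mk(i, ytr[i], sprintf("PT%03d", i)))
  yte <- rep(c(0, 1), 10)
  te <- lapply(seq_along(yte), function(i) mk(100 + i, yte[i], sprintf("PE%03d", i)))
  ev <- external_evaluate(tr, ytr, te, yte, models = "logistic", k = 4, seed = 1)
  expect_equal(nrow(ev$folds), 4)
  expect_true(all(ev$folds$roc_auc > 0.8))
})
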