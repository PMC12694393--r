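# brute-force reference implementations, independent of the package's
# vectorized code paths
brute_confusion <- function(y, yhat) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) tp <- tp + 1
    if (y[i] == 0 && yhat[i] == 1) fp <- fp + 1
    if (y[i] == 0 && yhat[i] == 0) tn <- tn + 1
    if (y[i] == 1 && yhat[i] == 0) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

brute_macro <- function(y, yhat) {
  pr <- c(); rc <- c()
  for (cls in c(0, 1)) {
    tp <- sum(y == cls & yhat == cls)
    pr <- c(pr, if (sum(yhat == cls) > 0) tp / sum(yhat == cls) else 0)
    rc <- c(rc, if (sum(y == cls) > 0) tp / sum(y == cls) else 0)
  }
  f1 <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  c(precision = mean(pr), recall = mean(rc), f1 = mean(f1))
}

test_that("confusion counts match direct enumeration", {
  d <- tibble::tibble(label = c(1, 1, 0, 0), .pred_class = c(1, 0, 0, 1))
  cm <- confusion_counts(d)
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]),
               c(tp = 1, fn = 1, tn = 1, fp = 1))
  perfect <- tibble::tibble(label = c(0, 1, 1), .pred_class = c(0, 1, 1))
  expect_equal(confusion_counts(perfect)$fp + confusion_counts(perfect)$fn, 0)
  all0 <- tibble::tibble(label = rep(c(0, 1), 5), .pred_class = 0)
  expect_equal(confusion_counts(all0)$tp, 0)
  expect_equal(confusion_counts(all0)$fn, 5)
})

test_that("worked macro-averaging example from first principles", {
  # tp=50, fp=10, tn=40, fn=0 with AF positive
  y <- rep(c(1, 0), c(50, 50))
  yhat <- c(rep(1, 50), rep(1, 10), rep(0, 40))
  m <- classification_metrics(tibble::tibble(label = y, .pred_class = yhat,
                                             .pred_AF = yhat))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, (50 / 60 + 1) / 2, tolerance = 1e-9) # 0.9167
  expect_equal(m$recall, (1 + 40 / 50) / 2, tolerance = 1e-9)    # 0.9
})

test_that("metrics agree with brute-force oracles on 1000 random sets", {
  set.seed(2024)
  proc_ok <- requireNamespace("pROC", quietly = TRUE)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    s <- round(runif(n), 2) # coarse scores exercise tie handling
    yhat <- as.integer(s > 0.5)
    d <- tibble::tibble(label = y, .pred_class = yhat, .pred_AF = s)
    m <- classification_metrics(d)
    cm <- confusion_counts(d)
    bc <- brute_confusion(y, yhat)
    expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]), bc,
                 ignore_attr = FALSE, tolerance = 0)
    expect_equal(m$accuracy, (bc["tp"] + bc["tn"]) / n, tolerance = 1e-9,
                 ignore_attr = TRUE)
    bm <- brute_macro(y, yhat)
    expect_equal(m$precision, bm[["precision"]], tolerance = 1e-9)
    expect_equal(m$recall, bm[["recall"]], tolerance = 1e-9)
    expect_equal(m$f1, bm[["f1"]], tolerance = 1e-9)
    expect_equal(m$auc_roc, brute_auc(y, s), tolerance = 1e-9)
  }
  # one spot check against an established implementation
  if (proc_ok) {
    set.seed(7)
    y <- rbinom(200, 1, 0.5); s <- runif(200)
    m <- classification_metrics(tibble::tibble(
      label = y, .pred_class = as.integer(s > 0.5), .pred_AF = s))
    auc_ref <- suppressMessages(as.numeric(pROC::auc(y, s)))
    expect_equal(m$auc_roc, auc_ref, tolerance = 1e-9)
  }
})

test_that("AUC hits its limit cases", {
  sep <- tibble::tibble(label = rep(c(0, 1), each = 50),
                        .pred_class = rep(c(0, 1), each = 50),
                        .pred_AF = c(runif(50, 0, 0.4), runif(50, 0.6, 1)))
  expect_equal(classification_metrics(sep)$auc_roc, 1)
  set.seed(31)
  rnd <- tibble::tibble(label = rbinom(4000, 1, 0.5), .pred_AF = runif(4000))
  rnd$.pred_class <- as.integer(rnd$.pred_AF > 0.5)
  expect_lt(abs(classification_metrics(rnd)$auc_roc - 0.5), 0.05)
  onecls <- tibble::tibble(label = rep(1, 5), .pred_class = 1, .pred_AF = 0.9)
  expect_true(is.na(classification_metrics(onecls)$auc_roc))
})

test_that("fold aggregation is an element-wise sum equal to pooling", {
  one <- tibble::tibble(tp = 1, fp = 2, tn = 3, fn = 4)
  five <- dplyr::bind_rows(rep(list(one), 5))
  agg <- aggregate_confusions(five)
  expect_equal(unlist(agg[c("tp", "fp", "tn", "fn")]),
               c(tp = 5, fp = 10, tn = 15, fn = 20))
  expect_equal(unlist(aggregate_confusions(one)[c("tp", "fp", "tn", "fn")]),
               unlist(one), ignore_attr = TRUE)
  # aggregation commutes with confusion on concatenated predictions
  set.seed(5)
  folds <- lapply(1:5, function(k) tibble::tibble(
    label = rbinom(40, 1, 0.5), .pred_class = rbinom(40, 1, 0.5)))
  per_fold <- dplyr::bind_rows(lapply(folds, confusion_counts))
  pooled <- confusion_counts(dplyr::bind_rows(folds))
  agg2 <- aggregate_confusions(per_fold)
  expect_equal(unlist(agg2[c("tp", "fp", "tn", "fn")]),
               unlist(pooled[c("tp", "fp", "tn", "fn")]))
  # row-normalized rates match pooled per-class rates
  expect_equal(agg2$tpr, pooled$tp / (pooled$tp + pooled$fn))
  expect_equal(agg2$tnr, pooled$tn / (pooled$tn + pooled$fp))
})

test_that("cross-fold summary reports mean and sample standard deviation", {
  same <- dplyr::bind_rows(rep(list(tibble::tibble(accuracy = 0.97)), 5))
  s <- summarize_folds(same, metrics = "accuracy")
  expect_equal(s$sd, 0)
  two <- tibble::tibble(accuracy = c(0.9, 1.0))
  s2 <- summarize_folds(two, metrics = "accuracy")
  expect_equal(s2$mean, 0.95)
  expect_equal(s2$sd, sqrt(0.005), tolerance = 1e-9) # ~0.0707, ddof = 1
  expect_error(summarize_folds(tibble::tibble(accuracy = 1)), "at least 2")
  set.seed(8)
  r <- tibble::tibble(accuracy = runif(5), loss = runif(5))
  s3 <- summarize_folds(r)
  expect_true(all(s3$mean >= vapply(r[s3$metric], min, 0) &
                    s3$mean <= vapply(r[s3$metric], max, 0)))
})

test_that("balanced symmetric evaluation makes all metrics coincide", {
  fx <- small_fit()
  pred <- evaluate_rr_cnn(fx$model, fx$test)
  m <- classification_metrics(pred)
  vals <- unlist(m[c("accuracy", "precision", "recall", "f1")])
  expect_lt(max(vals) - min(vals), 0.01)
})
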