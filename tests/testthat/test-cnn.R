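test_that("layer shapes match independent floor arithmetic for N = 25/50/100", {
  for (n in c(25, 50, 100)) {
    cfg <- rr_cnn_config(n)
    expect_equal(unlist(cnn_layer_sizes(cfg)), unlist(oracle_shapes(n)),
                 info = paste("N =", n))
  }
  # hand-checked anchors: 25 -> 23 -> 11 -> 9 -> 4 (x32 = 128)
  expect_equal(cnn_layer_sizes(rr_cnn_config(25))$flat, 128)
  expect_error(rr_cnn_config(5), "too small")
})

test_that("parameter count equals per-layer arithmetic, 10210 at N = 25", {
  for (n in c(25, 50, 100)) {
    expect_equal(count_parameters(rr_cnn_config(n)), oracle_param_count(n),
                 info = paste("N =", n))
  }
  expect_equal(count_parameters(rr_cnn_config(25)), 10210)
  # architecture is deterministic: two configs agree
  expect_equal(count_parameters(rr_cnn_config(100)),
               count_parameters(rr_cnn_config(100)))
})

test_that("softmax outputs are normalized probabilities, even untrained", {
  cfg <- rr_cnn_config(25)
  set.seed(5)
  params <- rrafnet:::.init_params(cfg)
  state <- rrafnet:::.init_state(cfg)
  X <- matrix(runif(10 * 25, 0.4, 1.2), 10)
  fw <- rrafnet:::.cnn_forward(params, state, cfg, X)
  expect_equal(rowSums(fw$probs), rep(1, 10), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- rr_cnn_config(10, dropout1 = 0, dropout2 = 0) # deterministic forward
  set.seed(11)
  params <- rrafnet:::.init_params(cfg)
  state <- rrafnet:::.init_state(cfg)
  B <- 6
  X <- matrix(runif(B * 10, 0.4, 1.2), B)
  y <- rep(c(0L, 1L), 3)
  Y <- diag(2)[y + 1, ]
  loss_at <- function(p) {
    fw <- rrafnet:::.cnn_forward(p, state, cfg, X, training = TRUE)
    -sum(Y * log(pmax(fw$probs, 1e-12))) / B
  }
  fw <- rrafnet:::.cnn_forward(params, state, cfg, X, training = TRUE)
  g <- rrafnet:::.cnn_backward(params, cfg, fw, Y)
  h <- 1e-5
  set.seed(12)
  for (nm in names(g)) {
    picks <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in picks) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = paste("grad", nm, i))
    }
  }
})

test_that("train/validation split is stratified, sized and seeded", {
  d <- tibble::tibble(label = rep(c(0L, 1L), each = 500), x = 1:1000)
  sp <- split_train_val(d, 0.2, seed = 3)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$val), 200)
  expect_lte(abs(sum(sp$val$label == 0) - sum(sp$val$label == 1)), 1)
  sp2 <- split_train_val(d, 0.2, seed = 3)
  expect_identical(sp$val$x, sp2$val$x)
  expect_error(split_train_val(tibble::tibble(label = rep(0L, 10)), 0.2, 1),
               "both classes")
})

test_that("training separates synthetic rhythms and honors early stopping", {
  fx <- small_fit()
  m <- fx$model
  expect_lte(m$stopped_epoch, 25)
  expect_equal(m$best_val_loss, min(m$history$val_loss)) # restore-best
  met <- classification_metrics(evaluate_rr_cnn(m, fx$test))
  expect_gte(met$accuracy, 0.9)
  h <- tidy(m)
  expect_named(h, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))
  expect_equal(glance(m)$n_parameters, 10210)
})

test_that("prediction is a pure function with the documented contract", {
  fx <- small_fit()
  X <- fx$test[rep(1, 3), ] # duplicated rows
  p <- predict(fx$model, X)
  expect_equal(p$.pred_SR + p$.pred_AF, rep(1, 3), tolerance = 1e-6)
  expect_equal(p$.pred_AF, rep(p$.pred_AF[1], 3))
  expect_error(predict(fx$model, matrix(0.8, 2, 10)), "does not match")
})

test_that("after training, variable windows score higher AF probability than flat ones", {
  fx <- small_fit()
  flat <- matrix(0.8, 1, 25)
  wild <- matrix(simulate_af_rr(25, mean_rr_s = 0.8, cv = 0.25, seed = 8), 1)
  p_flat <- predict(fx$model, flat)$.pred_AF
  p_wild <- predict(fx$model, wild)$.pred_AF
  expect_lt(p_flat, p_wild)
})

test_that("float32 serialization preserves architecture and predictions", {
  fx <- small_fit()
  path <- withr::local_tempfile()
  write_rr_cnn(fx$model, path)
  back <- read_rr_cnn(path)
  expect_identical(unclass(back$config), unclass(fx$model$config))
  expect_equal(back$n_parameters, fx$model$n_parameters)
  p0 <- predict(fx$model, fx$test)
  p1 <- predict(back, fx$test)
  expect_equal(p1$.pred_AF, p0$.pred_AF, tolerance = 1e-5)
  expect_identical(p1$.pred_class, p0$.pred_class)
})
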