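# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# A small trained model (N = 25) on an 8-subject synthetic cohort, reused by
# the cnn, quantization, evaluation and stream tests.
small_fit <- function() {
  if (is.null(.fixtures$model)) {
    co <- simulate_rr_cohort(n_subjects = 8, beats_per_subject = 1200,
                             seed = 101)
    b <- build_rr_datasets(co, lengths = 25, n_folds = 2, test_per_fold = 2,
                           seed = 101)
    .fixtures$train <- b$train[[1]]
    .fixtures$test <- b$test[[1]]
    .fixtures$model <- fit_rr_cnn(.fixtures$train, epochs = 25, seed = 101)
  }
  .fixtures
}

# independent per-layer arithmetic for the valid-padding architecture,
# kept separate from cnn_layer_sizes()/count_parameters()
oracle_shapes <- function(n, kernel = 3, pool = 2, f2 = 32) {
  l1 <- n - kernel + 1
  p1 <- floor((l1 - pool) / pool) + 1
  l2 <- p1 - kernel + 1
  p2 <- floor((l2 - pool) / pool) + 1
  list(conv1 = l1, pool1 = p1, conv2 = l2, pool2 = p2, flat = p2 * f2)
}

oracle_param_count <- function(n, k = 3, f1 = 16, f2 = 32, d = 64, cls = 2) {
  sh <- oracle_shapes(n, k)
  (k * 1 * f1 + f1) + 4 * f1 +        # conv1 + bn1 (incl. moving stats)
    (k * f1 * f2 + f2) + 4 * f2 +     # conv2 + bn2
    (sh$flat * d + d) +               # dense
    (d * cls + cls)                   # output
}
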