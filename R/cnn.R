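# Compact 1D convolutional network for RR-window classification, written in
# base-R matrix code. Convolutions are evaluated as im2col matrix products;
# batch normalization uses batch statistics in training and population
# statistics recalibrated over the training set at inference; optimization is Adam with early stopping on
# validation loss and best-weight restoration.

#' Configuration of the RR-window 1D-CNN
#'
#' Defines the fixed two-block architecture:
#' Input(N x 1) -> Conv1D(16, k=3) -> BatchNorm -> ReLU -> AvgPool(2) ->
#' Dropout(0.25) -> Conv1D(32, k=3) -> BatchNorm -> ReLU -> AvgPool(2) ->
#' Flatten -> Dense(64) -> ReLU -> Dropout(0.1) -> Dense(2) -> Softmax.
#'
#' @param n_rr Input window length N (number of RR intervals).
#' @param block1_filters,block2_filters Convolution filter counts (16, 32).
#' @param kernel Convolution kernel size (3).
#' @param pool Average-pooling size and stride (2).
#' @param dropout1,dropout2 Dropout rates after block 1 and the dense layer.
#' @param dense_units Width of the fully connected layer (64).
#' @param n_classes Output classes (2: sinus rhythm, AF).
#' @param padding `"valid"` (default) or `"same"` convolution padding.
#' @return A list of class `"rr_cnn_config"`.
#' @export
#' @examples
#' cfg <- rr_cnn_config(25)
#' count_parameters(cfg) # 10210
rr_cnn_config <- function(n_rr, block1_filters = 16, block2_filters = 32,
                          kernel = 3, pool = 2, dropout1 = 0.25,
                          dropout2 = 0.1, dense_units = 64, n_classes = 2,
                          padding = c("valid", "same")) {
  padding <- match.arg(padding)
  cfg <- list(n_rr = as.integer(n_rr), block1_filters = as.integer(block1_filters),
              block2_filters = as.integer(block2_filters),
              kernel = as.integer(kernel), pool = as.integer(pool),
              dropout1 = dropout1, dropout2 = dropout2,
              dense_units = as.integer(dense_units),
              n_classes = as.integer(n_classes), padding = padding)
  class(cfg) <- "rr_cnn_config"
  sh <- cnn_layer_sizes(cfg) # validates feasibility
  if (min(unlist(sh)) < 1) stop("window length ", n_rr, " too small for the architecture")
  cfg
}

#' Per-layer output lengths of the architecture
#'
#' @param cfg An [rr_cnn_config()].
#' @return A list with the temporal lengths after each stage (`conv1`,
#'   `pool1`, `conv2`, `pool2`) and the flattened feature length `flat`.
#' @export
cnn_layer_sizes <- function(cfg) {
  conv_out <- function(l) if (cfg$padding == "valid") l - cfg$kernel + 1L else l
  pool_out <- function(l) (l - cfg$pool) %/% cfg$pool + 1L
  l1 <- conv_out(cfg$n_rr)
  p1 <- pool_out(l1)
  l2 <- conv_out(p1)
  p2 <- pool_out(l2)
  list(conv1 = l1, pool1 = p1, conv2 = l2, pool2 = p2,
       flat = p2 * cfg$block2_filters)
}

#' Total parameter count of the network
#'
#' Counts trainable weights plus the non-trainable batch-norm moving
#' statistics, matching the usual framework bookkeeping.
#'
#' @param x An [rr_cnn_config()] or a fitted `rr_cnn` model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  cfg <- if (inherits(x, "rr_cnn")) x$config else x
  stopifnot(inherits(cfg, "rr_cnn_config"))
  sh <- cnn_layer_sizes(cfg)
  k <- cfg$kernel; f1 <- cfg$block1_filters; f2 <- cfg$block2_filters
  conv1 <- k * 1 * f1 + f1
  bn1 <- 4 * f1
  conv2 <- k * f1 * f2 + f2
  bn2 <- 4 * f2
  dense <- sh$flat * cfg$dense_units + cfg$dense_units
  out <- cfg$dense_units * cfg$n_classes + cfg$n_classes
  as.integer(conv1 + bn1 + conv2 + bn2 + dense + out)
}

# ---- internal layer machinery ------------------------------------------

.glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

.init_params <- function(cfg) {
  k <- cfg$kernel; f1 <- cfg$block1_filters; f2 <- cfg$block2_filters
  sh <- cnn_layer_sizes(cfg)
  list(
    conv1_w = matrix(.glorot(k * f1, k, k * f1), k, f1),
    conv1_b = numeric(f1),
    bn1_gamma = rep(1, f1), bn1_beta = numeric(f1),
    conv2_w = matrix(.glorot(k * f1 * f2, k * f1, k * f2), k * f1, f2),
    conv2_b = numeric(f2),
    bn2_gamma = rep(1, f2), bn2_beta = numeric(f2),
    dense_w = matrix(.glorot(sh$flat * cfg$dense_units, sh$flat,
                             cfg$dense_units), sh$flat, cfg$dense_units),
    dense_b = numeric(cfg$dense_units),
    out_w = matrix(.glorot(cfg$dense_units * cfg$n_classes, cfg$dense_units,
                           cfg$n_classes), cfg$dense_units, cfg$n_classes),
    out_b = numeric(cfg$n_classes)
  )
}

.init_state <- function(cfg) {
  list(bn1_mean = numeric(cfg$block1_filters),
       bn1_var = rep(1, cfg$block1_filters),
       bn2_mean = numeric(cfg$block2_filters),
       bn2_var = rep(1, cfg$block2_filters))
}

# linear indices turning a (B, L, C) array into the (B*Lo) x (K*C) im2col
# matrix; column j = (c-1)*K + k gathers input position t + k - 1, channel c
.im2col_idx <- function(B, L, C, K) {
  Lo <- L - K + 1L
  b_vec <- rep(seq_len(B), Lo)
  t_vec <- rep(seq_len(Lo), each = B)
  idx <- matrix(0L, B * Lo, K * C)
  for (c_ in seq_len(C)) {
    for (k_ in seq_len(K)) {
      idx[, (c_ - 1L) * K + k_] <-
        b_vec + B * (t_vec + k_ - 2L) + B * L * (c_ - 1L)
    }
  }
  as.integer(idx)
}

.conv_fwd <- function(X, W, b, idx, B, Lo) {
  f <- ncol(W)
  Xcol <- matrix(X[idx], B * Lo, nrow(W))
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = B * Lo)
  list(out = array(Y, c(B, Lo, f)), Xcol = Xcol)
}

.conv_bwd <- function(dY, Xcol, W, B, L, C, K, Lo) {
  f <- ncol(W)
  dYm <- matrix(dY, B * Lo, f)
  dW <- crossprod(Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, W)
  dX <- array(0, c(B, L, C))
  for (j in seq_len(K * C)) {
    c_ <- (j - 1L) %/% K + 1L
    k_ <- (j - 1L) %% K + 1L
    dX[, k_:(k_ + Lo - 1L), c_] <- dX[, k_:(k_ + Lo - 1L), c_] +
      matrix(dXcol[, j], B, Lo)
  }
  list(dX = dX, dW = dW, db = db)
}

.bn_eps <- 1e-3

.bn_fwd_train <- function(X, gamma, beta) {
  d <- dim(X); m <- d[1] * d[2]; f <- d[3]
  Xm <- matrix(X, m, f)
  mu <- colMeans(Xm)
  v <- colMeans(Xm * Xm) - mu^2
  ivar <- 1 / sqrt(v + .bn_eps)
  xhat <- (Xm - rep(mu, each = m)) * rep(ivar, each = m)
  Y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = array(Y, d), xhat = xhat, ivar = ivar, mu = mu, var = v)
}

.bn_fwd_infer <- function(X, gamma, beta, r_mean, r_var) {
  d <- dim(X); m <- d[1] * d[2]
  Xm <- matrix(X, m, d[3])
  ivar <- 1 / sqrt(r_var + .bn_eps)
  Y <- (Xm - rep(r_mean, each = m)) * rep(ivar * gamma, each = m) +
    rep(beta, each = m)
  array(Y, d)
}

.bn_bwd <- function(dY, xhat, ivar, gamma, dims) {
  m <- dims[1] * dims[2]; f <- dims[3]
  dYm <- matrix(dY, m, f)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dXm <- (dxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
    rep(ivar, each = m)
  list(dX = array(dXm, dims), dgamma = dgamma, dbeta = dbeta)
}

# Exact batch-norm calibration: population mean/variance of each BN layer's
# inputs over the full training set at the current weights. More reliable
# than momentum-tracked moving averages when training stops after a handful
# of epochs, and it is what the inference path actually needs.
.bn_recalibrate <- function(params, cfg, X, chunk = 1024L) {
  sh <- cnn_layer_sizes(cfg)
  k <- cfg$kernel; p <- cfg$pool
  acc <- function() list(s = 0, s2 = 0, n = 0)
  a1 <- acc(); a2 <- acc()
  upd <- function(a, Y, f) {
    Ym <- matrix(Y, ncol = f)
    a$s <- a$s + colSums(Ym); a$s2 <- a$s2 + colSums(Ym * Ym)
    a$n <- a$n + nrow(Ym)
    a
  }
  fin <- function(a) {
    mu <- a$s / a$n
    list(mean = mu, var = pmax(a$s2 / a$n - mu^2, 0))
  }
  # first pass: conv1 outputs
  for (start in seq(1, nrow(X), by = chunk)) {
    ix <- start:min(start + chunk - 1, nrow(X))
    B <- length(ix)
    Xa <- array(X[ix, , drop = FALSE], c(B, cfg$n_rr, 1L))
    cv1 <- .conv_fwd(Xa, params$conv1_w, params$conv1_b,
                     .im2col_idx(B, cfg$n_rr, 1L, k), B, sh$conv1)$out
    a1 <- upd(a1, cv1, cfg$block1_filters)
  }
  st1 <- fin(a1)
  # second pass: conv2 outputs with bn1 frozen at the just-computed stats
  for (start in seq(1, nrow(X), by = chunk)) {
    ix <- start:min(start + chunk - 1, nrow(X))
    B <- length(ix)
    Xa <- array(X[ix, , drop = FALSE], c(B, cfg$n_rr, 1L))
    cv1 <- .conv_fwd(Xa, params$conv1_w, params$conv1_b,
                     .im2col_idx(B, cfg$n_rr, 1L, k), B, sh$conv1)$out
    h <- .pool_fwd(pmax(.bn_fwd_infer(cv1, params$bn1_gamma, params$bn1_beta,
                                      st1$mean, st1$var), 0), p)
    cv2 <- .conv_fwd(h, params$conv2_w, params$conv2_b,
                     .im2col_idx(B, sh$pool1, cfg$block1_filters, k), B,
                     sh$conv2)$out
    a2 <- upd(a2, cv2, cfg$block2_filters)
  }
  st2 <- fin(a2)
  list(bn1_mean = st1$mean, bn1_var = st1$var,
       bn2_mean = st2$mean, bn2_var = st2$var)
}

.pool_fwd <- function(X, p) {
  d <- dim(X); P <- (d[2] - p) %/% p + 1L
  out <- array(0, c(d[1], P, d[3]))
  for (o in seq_len(p)) {
    out <- out + X[, seq(o, by = p, length.out = P), , drop = FALSE]
  }
  out / p
}

.pool_bwd <- function(dY, p, L) {
  d <- dim(dY); P <- d[2]
  dX <- array(0, c(d[1], L, d[3]))
  for (o in seq_len(p)) {
    dX[, seq(o, by = p, length.out = P), ] <- dY / p
  }
  dX
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass; training = TRUE caches intermediates and applies dropout
.cnn_forward <- function(params, state, cfg, X, training = FALSE,
                         idx_cache = NULL) {
  B <- nrow(X)
  sh <- cnn_layer_sizes(cfg)
  k <- cfg$kernel; p <- cfg$pool
  Xa <- array(X, c(B, cfg$n_rr, 1L))
  get_idx <- function(name, L, C) {
    if (!is.null(idx_cache)) {
      key <- paste(name, B, sep = "_")
      if (is.null(idx_cache[[key]])) idx_cache[[key]] <- .im2col_idx(B, L, C, k)
      idx_cache[[key]]
    } else .im2col_idx(B, L, C, k)
  }
  cache <- list(B = B, Xa = Xa)

  cv1 <- .conv_fwd(Xa, params$conv1_w, params$conv1_b,
                   get_idx("c1", cfg$n_rr, 1L), B, sh$conv1)
  if (training) {
    bn1 <- .bn_fwd_train(cv1$out, params$bn1_gamma, params$bn1_beta)
    a1 <- bn1$out
  } else {
    a1 <- .bn_fwd_infer(cv1$out, params$bn1_gamma, params$bn1_beta,
                        state$bn1_mean, state$bn1_var)
    bn1 <- NULL
  }
  r1 <- pmax(a1, 0)
  pl1 <- .pool_fwd(r1, p)
  if (training && cfg$dropout1 > 0) {
    m1 <- array((stats::runif(length(pl1)) >= cfg$dropout1) / (1 - cfg$dropout1),
                dim(pl1))
    d1 <- pl1 * m1
  } else {
    m1 <- NULL; d1 <- pl1
  }

  cv2 <- .conv_fwd(d1, params$conv2_w, params$conv2_b,
                   get_idx("c2", sh$pool1, cfg$block1_filters), B, sh$conv2)
  if (training) {
    bn2 <- .bn_fwd_train(cv2$out, params$bn2_gamma, params$bn2_beta)
    a2 <- bn2$out
  } else {
    a2 <- .bn_fwd_infer(cv2$out, params$bn2_gamma, params$bn2_beta,
                        state$bn2_mean, state$bn2_var)
    bn2 <- NULL
  }
  r2 <- pmax(a2, 0)
  pl2 <- .pool_fwd(r2, p)
  flat <- matrix(pl2, B, sh$flat)

  z1 <- flat %*% params$dense_w + rep(params$dense_b, each = B)
  h1 <- pmax(z1, 0)
  if (training && cfg$dropout2 > 0) {
    m2 <- matrix((stats::runif(length(h1)) >= cfg$dropout2) / (1 - cfg$dropout2),
                 nrow(h1), ncol(h1))
    h1d <- h1 * m2
  } else {
    m2 <- NULL; h1d <- h1
  }
  logits <- h1d %*% params$out_w + rep(params$out_b, each = B)
  probs <- .softmax(logits)

  if (training) {
    cache <- c(cache, list(cv1 = cv1, bn1 = bn1, r1 = r1, pl1 = pl1, m1 = m1,
                           d1 = d1, cv2 = cv2, bn2 = bn2, r2 = r2, pl2 = pl2,
                           flat = flat, z1 = z1, h1 = h1, m2 = m2, h1d = h1d,
                           sh = sh))
  }
  list(probs = probs, logits = logits, cache = cache)
}

# backward pass from softmax cross-entropy; Y is the one-hot label matrix
.cnn_backward <- function(params, cfg, fw, Y) {
  ch <- fw$cache
  B <- ch$B; sh <- ch$sh; k <- cfg$kernel; p <- cfg$pool
  g <- list()
  dZ <- (fw$probs - Y) / B
  g$out_w <- crossprod(ch$h1d, dZ)
  g$out_b <- colSums(dZ)
  dH1d <- tcrossprod(dZ, params$out_w)
  if (!is.null(ch$m2)) dH1d <- dH1d * ch$m2
  dZ1 <- dH1d * (ch$z1 > 0)
  g$dense_w <- crossprod(ch$flat, dZ1)
  g$dense_b <- colSums(dZ1)
  dFlat <- tcrossprod(dZ1, params$dense_w)
  dPl2 <- array(dFlat, c(B, sh$pool2, cfg$block2_filters))
  dR2 <- .pool_bwd(dPl2, p, sh$conv2)
  dA2 <- dR2 * (ch$r2 > 0)
  bn2b <- .bn_bwd(dA2, ch$bn2$xhat, ch$bn2$ivar, params$bn2_gamma,
                  c(B, sh$conv2, cfg$block2_filters))
  g$bn2_gamma <- bn2b$dgamma; g$bn2_beta <- bn2b$dbeta
  cv2b <- .conv_bwd(bn2b$dX, ch$cv2$Xcol, params$conv2_w, B, sh$pool1,
                    cfg$block1_filters, k, sh$conv2)
  g$conv2_w <- cv2b$dW; g$conv2_b <- cv2b$db
  dD1 <- cv2b$dX
  if (!is.null(ch$m1)) dD1 <- dD1 * ch$m1
  dR1 <- .pool_bwd(dD1, p, sh$conv1)
  dA1 <- dR1 * (ch$r1 > 0)
  bn1b <- .bn_bwd(dA1, ch$bn1$xhat, ch$bn1$ivar, params$bn1_gamma,
                  c(B, sh$conv1, cfg$block1_filters))
  g$bn1_gamma <- bn1b$dgamma; g$bn1_beta <- bn1b$dbeta
  cv1b <- .conv_bwd(bn1b$dX, ch$cv1$Xcol, params$conv1_w, B, cfg$n_rr, 1L, k,
                    sh$conv1)
  g$conv1_w <- cv1b$dW; g$conv1_b <- cv1b$db
  g
}

.feature_matrix <- function(data, n_rr = NULL) {
  feat <- grep("^rr_\\d+$", names(data), value = TRUE)
  if (length(feat) == 0) stop("no rr_### feature columns found")
  feat <- feat[order(as.integer(sub("rr_", "", feat)))]
  if (!is.null(n_rr) && length(feat) != n_rr) {
    stop("input has ", length(feat), " RR features but the model expects ", n_rr)
  }
  as.matrix(data[, feat, drop = FALSE])
}

#' Stratified train/validation split
#'
#' Splits a window table into training and validation parts at random,
#' stratified by `label` so both sides keep the class mix (seeded).
#'
#' @param data A window tibble with a binary `label` column.
#' @param val_fraction Fraction assigned to validation (default 0.2).
#' @param seed Integer seed.
#' @return A list with `train` and `val` tibbles.
#' @export
split_train_val <- function(data, val_fraction = 0.2, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, "label" %in% names(data),
            nrow(data) >= 2)
  if (length(unique(data$label)) < 2) {
    stop("both classes must be present for a stratified split")
  }
  set.seed(seed)
  val_idx <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(ix) {
    sample(ix, round(length(ix) * val_fraction))
  }))
  list(train = tibble::as_tibble(data[-val_idx, , drop = FALSE]),
       val = tibble::as_tibble(data[sort(val_idx), , drop = FALSE]))
}

#' Fit the RR-window 1D-CNN
#'
#' Trains the two-block convolutional classifier on a window table with Adam
#' (learning rate 0.0009, beta1 0.9, beta2 0.999), categorical cross-entropy,
#' batches of 32 and at most 100 epochs. An internal stratified 80/20
#' train/validation split monitors validation loss; training stops early when
#' it fails to improve for `patience` consecutive epochs and the
#' best-validation-loss weights are restored. All randomness (weight
#' initialization, shuffling, dropout, the split) derives from `seed`.
#'
#' @param data Window tibble with feature columns `rr_001..rr_N` (raw RR
#'   values in seconds; no normalization is applied) and a binary `label`
#'   (0 = sinus rhythm, 1 = AF).
#' @param config Optional [rr_cnn_config()]; defaults to the standard
#'   architecture at the data's window length.
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate,beta1,beta2 Adam hyperparameters
#'   (defaults 0.0009, 0.9, 0.999).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param min_delta Minimum validation-loss improvement counted as progress
#'   (default 0).
#' @param val_fraction Validation fraction of the internal split (default 0.2).
#' @param seed Integer seed.
#' @param verbose Print one line per epoch.
#' @return An object of class `"rr_cnn"`: list with `config`, `params`,
#'   `state` (calibrated batch-norm population statistics), `history` (per-epoch tibble),
#'   `stopped_epoch`, `best_epoch` and `n_parameters`.
#' @export
fit_rr_cnn <- function(data, config = NULL, epochs = 100, batch_size = 32,
                       learning_rate = 9e-4, beta1 = 0.9, beta2 = 0.999,
                       patience = 5, min_delta = 0, val_fraction = 0.2,
                       seed = 1L, verbose = FALSE) {
  X_all <- .feature_matrix(data)
  cfg <- if (is.null(config)) rr_cnn_config(ncol(X_all)) else config
  if (ncol(X_all) != cfg$n_rr) stop("config n_rr does not match the data")
  stopifnot("label" %in% names(data))

  sp <- split_train_val(data, val_fraction, seed)
  Xtr <- .feature_matrix(sp$train, cfg$n_rr)
  ytr <- as.integer(sp$train$label)
  Xva <- .feature_matrix(sp$val, cfg$n_rr)
  yva <- as.integer(sp$val$label)
  Ytr <- diag(cfg$n_classes)[ytr + 1L, , drop = FALSE]

  set.seed(seed)
  params <- .init_params(cfg)
  state <- .init_state(cfg)
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  step <- 0L
  eps <- 1e-7
  idx_cache <- new.env(parent = emptyenv())

  n <- nrow(Xtr)
  history <- vector("list", epochs)
  best <- list(loss = Inf, epoch = 0L, params = NULL, state = NULL)
  wait <- 0L
  stopped <- epochs

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, n)]
      Xb <- Xtr[bi, , drop = FALSE]
      Yb <- Ytr[bi, , drop = FALSE]
      fw <- .cnn_forward(params, state, cfg, Xb, training = TRUE,
                         idx_cache = idx_cache)
      pb <- pmax(fw$probs, 1e-12)
      loss_b <- -sum(Yb * log(pb)) / nrow(Xb)
      if (!is.finite(loss_b)) stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + loss_b * nrow(Xb)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs) == max.col(Yb))
      g <- .cnn_backward(params, cfg, fw, Yb)
      step <- step + 1L
      lr_t <- learning_rate * sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in names(g)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
      }
    }
    state <- .bn_recalibrate(params, cfg, Xtr)
    val <- .cnn_eval(params, state, cfg, Xva, yva, idx_cache)
    history[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
      val_loss = val$loss, val_accuracy = val$accuracy)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f acc %.4f  val_loss %.4f val_acc %.4f",
                      ep, ep_loss / n, ep_correct / n, val$loss, val$accuracy))
    }
    if (val$loss < best$loss - min_delta) {
      best <- list(loss = val$loss, epoch = ep, params = params, state = state,
                   val_accuracy = val$accuracy)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stopped <- ep; break }
    }
  }

  model <- structure(list(
    config = cfg,
    params = best$params %||% params,
    state = best$state %||% state,
    history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
    stopped_epoch = stopped,
    best_epoch = best$epoch,
    best_val_loss = best$loss,
    best_val_accuracy = best$val_accuracy %||% NA_real_,
    n_parameters = count_parameters(cfg),
    seed = seed
  ), class = "rr_cnn")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cnn_eval <- function(params, state, cfg, X, y, idx_cache = NULL,
                      chunk = 512L) {
  n <- nrow(X); loss <- 0; correct <- 0
  for (start in seq(1, n, by = chunk)) {
    ix <- start:min(start + chunk - 1, n)
    fw <- .cnn_forward(params, state, cfg, X[ix, , drop = FALSE],
                       training = FALSE, idx_cache = idx_cache)
    p <- pmax(fw$probs, 1e-12)
    loss <- loss - sum(log(p[cbind(seq_along(ix), y[ix] + 1L)]))
    correct <- correct + sum((max.col(fw$probs) - 1L) == y[ix])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Predict with a fitted RR-window CNN
#'
#' @param object A fitted `rr_cnn`.
#' @param new_data Window tibble (or matrix) with `rr_001..rr_N` features.
#' @param ... Unused.
#' @return A tibble with columns `.pred_SR`, `.pred_AF` (softmax
#'   probabilities, rows summing to 1) and `.pred_class` (0/1 argmax).
#' @export
predict.rr_cnn <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) new_data else
    .feature_matrix(new_data, object$config$n_rr)
  if (ncol(X) != object$config$n_rr) {
    stop("input window length ", ncol(X), " does not match model length ",
         object$config$n_rr)
  }
  n <- nrow(X)
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = 512L)) {
    ix <- start:min(start + 511L, n)
    fw <- .cnn_forward(object$params, object$state, object$config,
                       X[ix, , drop = FALSE], training = FALSE)
    probs[ix, ] <- fw$probs
  }
  tibble::tibble(.pred_SR = probs[, 1], .pred_AF = probs[, 2],
                 .pred_class = as.integer(max.col(probs) - 1L))
}

#' @export
print.rr_cnn <- function(x, ...) {
  sh <- cnn_layer_sizes(x$config)
  cat("RR-window 1D-CNN (", x$config$n_rr, " RR intervals, ",
      x$n_parameters, " parameters)\n", sep = "")
  cat("  conv ", x$config$block1_filters, "@", sh$conv1, " -> pool ", sh$pool1,
      " -> conv ", x$config$block2_filters, "@", sh$conv2, " -> pool ",
      sh$pool2, " -> dense ", x$config$dense_units, " -> softmax\n", sep = "")
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat("  trained ", nrow(x$history), " epochs (best epoch ", x$best_epoch,
        ", val loss ", signif(x$best_val_loss, 4), ")\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted RR CNN
#'
#' @param x A fitted `rr_cnn`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`.
#' @method tidy rr_cnn
#' @export
tidy.rr_cnn <- function(x, ...) x$history

#' One-row summary of a fitted RR CNN
#'
#' @param x A fitted `rr_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: window length, parameter count, epochs run,
#'   best epoch and best validation loss/accuracy.
#' @method glance rr_cnn
#' @export
glance.rr_cnn <- function(x, ...) {
  tibble::tibble(
    n_rr = x$config$n_rr,
    n_parameters = x$n_parameters,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_accuracy = x$best_val_accuracy
  )
}

# ---- serialization ------------------------------------------------------

.param_order <- c("conv1_w", "conv1_b", "bn1_gamma", "bn1_beta",
                  "conv2_w", "conv2_b", "bn2_gamma", "bn2_beta",
                  "dense_w", "dense_b", "out_w", "out_b")
.state_order <- c("bn1_mean", "bn1_var", "bn2_mean", "bn2_var")

#' Serialize a float32 RR CNN to a binary file
#'
#' Weights and batch-norm statistics are stored as 4-byte floats, the
#' configuration as a small integer header — mirroring the footprint of a
#' float32 deployment artifact.
#'
#' @param model A fitted `rr_cnn`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr_cnn <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RRCNN32!"), con)
  cfg <- model$config
  writeBin(as.integer(c(cfg$n_rr, cfg$block1_filters, cfg$block2_filters,
                        cfg$kernel, cfg$pool, cfg$dense_units, cfg$n_classes,
                        cfg$padding == "same")), con, size = 4)
  for (nm in c(.param_order)) {
    v <- model$params[[nm]]
    writeBin(as.integer(length(v)), con, size = 4)
    writeBin(as.numeric(v), con, size = 4)
  }
  for (nm in .state_order) {
    v <- model$state[[nm]]
    writeBin(as.integer(length(v)), con, size = 4)
    writeBin(as.numeric(v), con, size = 4)
  }
  invisible(path)
}

#' Load a float32 RR CNN written by [write_rr_cnn()]
#'
#' @param path File path.
#' @return An `rr_cnn` model (without training history).
#' @export
read_rr_cnn <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "RRCNN32!") stop("not a float32 RR-CNN file: ", path)
  h <- readBin(con, "integer", 8, size = 4)
  cfg <- rr_cnn_config(h[1], h[2], h[3], h[4], h[5], dense_units = h[6],
                       n_classes = h[7],
                       padding = if (h[8] == 1) "same" else "valid")
  shp <- .param_shapes(cfg)
  params <- list(); state <- list()
  for (nm in .param_order) {
    len <- readBin(con, "integer", 1, size = 4)
    v <- readBin(con, "numeric", len, size = 4)
    params[[nm]] <- if (is.null(shp[[nm]])) v else
      matrix(v, shp[[nm]][1], shp[[nm]][2])
  }
  for (nm in .state_order) {
    len <- readBin(con, "integer", 1, size = 4)
    state[[nm]] <- readBin(con, "numeric", len, size = 4)
  }
  structure(list(config = cfg, params = params, state = state,
                 history = NULL, stopped_epoch = NA_integer_,
                 best_epoch = NA_integer_, best_val_loss = NA_real_,
                 best_val_accuracy = NA_real_,
                 n_parameters = count_parameters(cfg), seed = NA_integer_),
            class = "rr_cnn")
}

.param_shapes <- function(cfg) {
  sh <- cnn_layer_sizes(cfg)
  list(conv1_w = c(cfg$kernel, cfg$block1_filters),
       conv2_w = c(cfg$kernel * cfg$block1_filters, cfg$block2_filters),
       dense_w = c(sh$flat, cfg$dense_units),
       out_w = c(cfg$dense_units, cfg$n_classes))
}
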