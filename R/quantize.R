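# Full-integer post-training quantization of the RR-window CNN.
# Batch-norm layers are folded into the preceding convolutions; weights are
# quantized per-tensor to symmetric int8, activations to asymmetric int8
# with ranges calibrated on a representative window set, and biases to int32
# at the product scale. Inference simulates the integer pipeline by
# quantize/dequantize at every tensor boundary, reproducing the rounding and
# saturation a deployed int8 interpreter applies.

.qparams_act <- function(lo, hi) {
  lo <- min(lo, 0); hi <- max(hi, 0) # int8 range must contain zero
  scale <- (hi - lo) / 255
  if (scale <= 0) return(list(scale = 1, zero_point = 0L))
  zp <- round(-128 - lo / scale)
  list(scale = scale, zero_point = as.integer(min(max(zp, -128), 127)))
}

.quant_act <- function(x, qp) {
  q <- round(x / qp$scale) + qp$zero_point
  q <- pmin(pmax(q, -128), 127)
  (q - qp$zero_point) * qp$scale
}

.quant_weight <- function(w) {
  scale <- max(abs(w)) / 127
  if (scale == 0) scale <- 1
  q <- pmin(pmax(round(w / scale), -127), 127)
  list(q = q, scale = scale, deq = q * scale)
}

.quant_bias <- function(b, scale) {
  q <- round(b / scale)
  list(q = q, scale = scale, deq = q * scale)
}

# fold batch norm into the preceding convolution: y = gamma*(conv-mu)/sd + beta
.fold_bn <- function(W, b, gamma, beta, r_mean, r_var) {
  s <- gamma / sqrt(r_var + .bn_eps)
  list(W = sweep(W, 2, s, `*`), b = (b - r_mean) * s + beta)
}

# forward pass of the BN-folded float network, optionally recording
# activation ranges (calibration) or applying fake-quantization (inference)
.folded_forward <- function(fq, X, mode = c("calibrate", "quantized", "float"),
                            ranges = NULL) {
  mode <- match.arg(mode)
  cfg <- fq$config
  sh <- cnn_layer_sizes(cfg)
  B <- nrow(X)
  k <- cfg$kernel; p <- cfg$pool
  obs <- list()
  touch <- function(name, x) {
    if (mode == "calibrate") obs[[name]] <<- range(x)
    if (mode == "quantized") x <- .quant_act(x, ranges[[name]])
    x
  }
  Xa <- array(touch("input", X), c(B, cfg$n_rr, 1L))
  a1 <- .conv_fwd(Xa, fq$conv1_w, fq$conv1_b,
                  .im2col_idx(B, cfg$n_rr, 1L, k), B, sh$conv1)$out
  a1 <- touch("act1", pmax(a1, 0))
  p1 <- touch("pool1", .pool_fwd(a1, p))
  a2 <- .conv_fwd(p1, fq$conv2_w, fq$conv2_b,
                  .im2col_idx(B, sh$pool1, cfg$block1_filters, k), B,
                  sh$conv2)$out
  a2 <- touch("act2", pmax(a2, 0))
  p2 <- touch("pool2", .pool_fwd(a2, p))
  flat <- matrix(p2, B, sh$flat)
  h1 <- touch("dense1", pmax(flat %*% fq$dense_w + rep(fq$dense_b, each = B), 0))
  logits <- touch("logits", h1 %*% fq$out_w + rep(fq$out_b, each = B))
  list(probs = .softmax(logits), obs = obs)
}

#' Post-training INT8 quantization of a fitted RR CNN
#'
#' Converts a trained float32 network to a full-integer int8 representation:
#' batch norm is folded into the convolutions, weights become per-tensor
#' symmetric int8, biases int32, and activation ranges are calibrated on a
#' seeded representative sample of training windows. The returned object
#' predicts through the simulated integer pipeline and serializes to roughly
#' a quarter of the float32 artifact.
#'
#' @param model A fitted `rr_cnn`.
#' @param representative Window tibble the calibration sample is drawn from
#'   (normally the training table).
#' @param n_rep Number of calibration windows (default 200).
#' @param seed Seed for the calibration draw.
#' @return An object of class `"rr_cnn_int8"` holding the quantized tensors,
#'   per-tensor scales/zero-points, calibrated activation ranges and a
#'   descriptor of the representative set.
#' @export
quantize_rr_cnn <- function(model, representative, n_rep = 200, seed = 1L) {
  stopifnot(inherits(model, "rr_cnn"))
  X <- .feature_matrix(representative, model$config$n_rr)
  if (nrow(X) == 0) stop("representative set is empty")
  set.seed(seed)
  take <- if (nrow(X) > n_rep) sort(sample.int(nrow(X), n_rep)) else
    seq_len(nrow(X))
  Xrep <- X[take, , drop = FALSE]

  p <- model$params; s <- model$state
  f1 <- .fold_bn(p$conv1_w, p$conv1_b, p$bn1_gamma, p$bn1_beta,
                 s$bn1_mean, s$bn1_var)
  f2 <- .fold_bn(p$conv2_w, p$conv2_b, p$bn2_gamma, p$bn2_beta,
                 s$bn2_mean, s$bn2_var)
  folded <- list(config = model$config,
                 conv1_w = f1$W, conv1_b = f1$b,
                 conv2_w = f2$W, conv2_b = f2$b,
                 dense_w = p$dense_w, dense_b = p$dense_b,
                 out_w = p$out_w, out_b = p$out_b)

  cal <- .folded_forward(folded, Xrep, mode = "calibrate")$obs
  ranges <- lapply(cal, function(r) .qparams_act(r[1], r[2]))

  qw <- list(conv1_w = .quant_weight(folded$conv1_w),
             conv2_w = .quant_weight(folded$conv2_w),
             dense_w = .quant_weight(folded$dense_w),
             out_w = .quant_weight(folded$out_w))
  in_scale <- c(conv1_w = ranges$input$scale, conv2_w = ranges$pool1$scale,
                dense_w = ranges$pool2$scale, out_w = ranges$dense1$scale)
  qb <- list(
    conv1_b = .quant_bias(folded$conv1_b, qw$conv1_w$scale * in_scale[["conv1_w"]]),
    conv2_b = .quant_bias(folded$conv2_b, qw$conv2_w$scale * in_scale[["conv2_w"]]),
    dense_b = .quant_bias(folded$dense_b, qw$dense_w$scale * in_scale[["dense_w"]]),
    out_b = .quant_bias(folded$out_b, qw$out_w$scale * in_scale[["out_w"]])
  )

  structure(list(
    config = model$config,
    weights = qw,
    biases = qb,
    act_ranges = ranges,
    representative = list(n = nrow(Xrep), seed = seed),
    n_parameters = count_parameters(model$config)
  ), class = "rr_cnn_int8")
}

.int8_folded <- function(object) {
  list(config = object$config,
       conv1_w = object$weights$conv1_w$deq, conv1_b = object$biases$conv1_b$deq,
       conv2_w = object$weights$conv2_w$deq, conv2_b = object$biases$conv2_b$deq,
       dense_w = object$weights$dense_w$deq, dense_b = object$biases$dense_b$deq,
       out_w = object$weights$out_w$deq, out_b = object$biases$out_b$deq)
}

#' Predict with an INT8-quantized RR CNN
#'
#' Runs the simulated integer pipeline: inputs, weights and every
#' intermediate activation pass through their int8 grid before the next
#' layer. The output contract matches [predict.rr_cnn()].
#'
#' @param object An `rr_cnn_int8` from [quantize_rr_cnn()].
#' @param new_data Window tibble or matrix with `rr_001..rr_N` features.
#' @param ... Unused.
#' @return A tibble with `.pred_SR`, `.pred_AF` and `.pred_class`.
#' @export
predict.rr_cnn_int8 <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) new_data else
    .feature_matrix(new_data, object$config$n_rr)
  if (ncol(X) != object$config$n_rr) {
    stop("input window length ", ncol(X), " does not match model length ",
         object$config$n_rr)
  }
  fq <- .int8_folded(object)
  n <- nrow(X)
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = 512L)) {
    ix <- start:min(start + 511L, n)
    probs[ix, ] <- .folded_forward(fq, X[ix, , drop = FALSE],
                                   mode = "quantized",
                                   ranges = object$act_ranges)$probs
  }
  tibble::tibble(.pred_SR = probs[, 1], .pred_AF = probs[, 2],
                 .pred_class = as.integer(max.col(probs) - 1L))
}

#' @export
print.rr_cnn_int8 <- function(x, ...) {
  cat("INT8 RR-window 1D-CNN (", x$config$n_rr, " RR intervals, ",
      x$n_parameters, " parameters)\n", sep = "")
  cat("  calibrated on ", x$representative$n, " representative windows",
      " (seed ", x$representative$seed, ")\n", sep = "")
  invisible(x)
}

#' Serialize an INT8 RR CNN to a binary file
#'
#' Weight tensors are stored as single bytes, biases as 4-byte integers and
#' scales/zero-points as 4-byte floats, so the artifact is roughly a quarter
#' the size of its float32 counterpart from [write_rr_cnn()]. Serialization
#' is deterministic: the same quantized model always yields identical bytes.
#'
#' @param object An `rr_cnn_int8`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr_cnn_int8 <- function(object, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RRCNNI8!"), con)
  cfg <- object$config
  writeBin(as.integer(c(cfg$n_rr, cfg$block1_filters, cfg$block2_filters,
                        cfg$kernel, cfg$pool, cfg$dense_units, cfg$n_classes,
                        cfg$padding == "same")), con, size = 4)
  for (nm in names(object$weights)) {
    w <- object$weights[[nm]]
    writeBin(as.integer(length(w$q)), con, size = 4)
    writeBin(as.numeric(w$scale), con, size = 4)
    writeBin(as.integer(w$q), con, size = 1)
  }
  for (nm in names(object$biases)) {
    b <- object$biases[[nm]]
    writeBin(as.integer(length(b$q)), con, size = 4)
    writeBin(as.numeric(b$scale), con, size = 4)
    writeBin(as.integer(b$q), con, size = 4)
  }
  for (nm in names(object$act_ranges)) {
    r <- object$act_ranges[[nm]]
    writeBin(as.numeric(r$scale), con, size = 4)
    writeBin(as.integer(r$zero_point), con, size = 1)
  }
  invisible(path)
}

#' Load an INT8 RR CNN written by [write_rr_cnn_int8()]
#'
#' @param path File path.
#' @return An `rr_cnn_int8` object.
#' @export
read_rr_cnn_int8 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "RRCNNI8!") stop("not an INT8 RR-CNN file: ", path)
  h <- readBin(con, "integer", 8, size = 4)
  cfg <- rr_cnn_config(h[1], h[2], h[3], h[4], h[5], dense_units = h[6],
                       n_classes = h[7],
                       padding = if (h[8] == 1) "same" else "valid")
  shp <- .param_shapes(cfg)
  wn <- c("conv1_w", "conv2_w", "dense_w", "out_w")
  bn <- c("conv1_b", "conv2_b", "dense_b", "out_b")
  an <- c("input", "act1", "pool1", "act2", "pool2", "dense1", "logits")
  weights <- list(); biases <- list(); ranges <- list()
  for (nm in wn) {
    len <- readBin(con, "integer", 1, size = 4)
    scale <- readBin(con, "numeric", 1, size = 4)
    q <- readBin(con, "integer", len, size = 1)
    q <- matrix(q, shp[[nm]][1], shp[[nm]][2])
    weights[[nm]] <- list(q = q, scale = scale, deq = q * scale)
  }
  for (nm in bn) {
    len <- readBin(con, "integer", 1, size = 4)
    scale <- readBin(con, "numeric", 1, size = 4)
    q <- readBin(con, "integer", len, size = 4)
    biases[[nm]] <- list(q = q, scale = scale, deq = q * scale)
  }
  for (nm in an) {
    scale <- readBin(con, "numeric", 1, size = 4)
    zp <- readBin(con, "integer", 1, size = 1)
    ranges[[nm]] <- list(scale = scale, zero_point = as.integer(zp))
  }
  structure(list(config = cfg, weights = weights, biases = biases,
                 act_ranges = ranges,
                 representative = list(n = NA_integer_, seed = NA_integer_),
                 n_parameters = count_parameters(cfg)),
            class = "rr_cnn_int8")
}
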