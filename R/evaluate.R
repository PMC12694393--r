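#' Confusion counts with AF as the positive class
#'
#' @param data A data frame of per-window predictions.
#' @param truth,estimate Columns holding the true and predicted binary labels
#'   (0 = sinus rhythm, 1 = AF); defaults `label` and `.pred_class`.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn` and `n`.
#' @export
#' @examples
#' confusion_counts(tibble::tibble(label = c(1, 1, 0, 0),
#'                                 .pred_class = c(1, 0, 0, 1)))
confusion_counts <- function(data, truth = label, estimate = .pred_class) {
  y <- dplyr::pull(data, {{ truth }})
  yhat <- dplyr::pull(data, {{ estimate }})
  if (length(y) != length(yhat)) stop("truth and estimate lengths differ")
  tibble::tibble(
    tp = sum(y == 1 & yhat == 1),
    fp = sum(y == 0 & yhat == 1),
    tn = sum(y == 0 & yhat == 0),
    fn = sum(y == 1 & yhat == 0),
    n = length(y)
  )
}

# midrank (Wilcoxon) AUC: P(score_AF > score_SR) + 0.5 P(tie)
.auc_midrank <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one evaluated fold
#'
#' Computes accuracy, macro-averaged precision/recall/F1 (per class, then
#' averaged — on balanced test tables this coincides with accuracy for a
#' symmetric classifier), rank-based AUC-ROC (midrank tie handling) and mean
#' categorical cross-entropy loss.
#'
#' @param data Per-window predictions.
#' @param truth,estimate,score Columns with the true label, predicted label
#'   and AF probability; defaults `label`, `.pred_class`, `.pred_AF`.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc_roc`, `loss`, `n`. AUC is `NA` when a class is absent.
#' @export
classification_metrics <- function(data, truth = label,
                                   estimate = .pred_class,
                                   score = .pred_AF) {
  y <- dplyr::pull(data, {{ truth }})
  yhat <- dplyr::pull(data, {{ estimate }})
  s <- dplyr::pull(data, {{ score }})
  if (length(y) == 0) stop("no predictions to evaluate")
  cm <- confusion_counts(tibble::tibble(label = y, .pred_class = yhat))
  per_class <- function(pos) {
    tp <- sum(y == pos & yhat == pos)
    fp <- sum(y != pos & yhat == pos)
    fn <- sum(y == pos & yhat != pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(prec = prec, rec = rec)
  }
  c0 <- per_class(0); c1 <- per_class(1)
  precision <- (c0[["prec"]] + c1[["prec"]]) / 2
  recall <- (c0[["rec"]] + c1[["rec"]]) / 2
  f1c <- function(pr, rc) if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  f1 <- (f1c(c0[["prec"]], c0[["rec"]]) + f1c(c1[["prec"]], c1[["rec"]])) / 2
  p_clip <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p_clip) + (1 - y) * log(1 - p_clip))
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / cm$n,
    precision = precision,
    recall = recall,
    f1 = f1,
    auc_roc = .auc_midrank(y, s),
    loss = loss,
    n = cm$n
  )
}

#' Sum per-fold confusion matrices into one aggregate
#'
#' With subject-wise folds the test sets are disjoint in subjects, so the
#' element-wise sum of per-fold confusion matrices is the confusion matrix of
#' all pooled test predictions.
#'
#' @param cms A tibble of confusion rows (columns `tp`, `fp`, `tn`, `fn`).
#' @return A one-row tibble with summed counts and per-class rates
#'   `tpr` (AF windows called AF) and `tnr` (SR windows called SR).
#' @export
aggregate_confusions <- function(cms) {
  stopifnot(nrow(cms) >= 1, all(c("tp", "fp", "tn", "fn") %in% names(cms)))
  out <- tibble::tibble(
    tp = sum(cms$tp), fp = sum(cms$fp), tn = sum(cms$tn), fn = sum(cms$fn))
  out$n <- out$tp + out$fp + out$tn + out$fn
  out$tpr <- out$tp / (out$tp + out$fn)
  out$tnr <- out$tn / (out$tn + out$fp)
  out
}

#' Cross-fold mean and standard deviation of metrics
#'
#' @param reports A tibble of per-fold metric rows (one row per fold, metric
#'   columns such as those from [classification_metrics()]).
#' @param metrics Which columns to summarize (default: the standard six).
#' @return A tibble with columns `metric`, `mean`, `sd` (sample SD, n-1
#'   denominator) and `n_folds`.
#' @export
summarize_folds <- function(reports,
                            metrics = c("accuracy", "precision", "recall",
                                        "f1", "auc_roc", "loss")) {
  metrics <- intersect(metrics, names(reports))
  if (nrow(reports) < 2) stop("need at least 2 folds to compute a spread")
  reports |>
    dplyr::select(dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_folds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metrics))
}

#' Evaluate a model on a test window table
#'
#' Convenience wrapper: predicts, then binds the predictions to the truth.
#'
#' @param model An `rr_cnn` or `rr_cnn_int8`.
#' @param test Window tibble with `rr_001..rr_N` and `label`.
#' @return The test tibble's `subject_id` (if present) and `label` columns
#'   with `.pred_SR`, `.pred_AF`, `.pred_class` bound on.
#' @export
evaluate_rr_cnn <- function(model, test) {
  pred <- stats::predict(model, test)
  keep <- intersect(c("subject_id", "window_index", "label"), names(test))
  dplyr::bind_cols(tibble::as_tibble(test[, keep, drop = FALSE]), pred)
}
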