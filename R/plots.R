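#' Training-history curves of a fitted RR CNN
#'
#' Loss and accuracy per epoch for the training and internal validation
#' splits, the usual convergence diagnostic.
#'
#' @param object A fitted `rr_cnn` with a training history.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_cnn
#' @export
autoplot.rr_cnn <- function(object, ...) {
  h <- object$history
  if (is.null(h) || nrow(h) == 0) stop("model has no training history")
  long <- h |>
    tidyr::pivot_longer(-"epoch", names_to = "series") |>
    dplyr::mutate(
      split = ifelse(startsWith(.data$series, "val_"), "validation", "training"),
      measure = sub("^val_", "", .data$series)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = sprintf("RR CNN training (N = %d)",
                                  object$config$n_rr)) +
    ggplot2::theme_minimal()
}

#' Heatmap of an aggregated confusion matrix
#'
#' @param cm A one-row confusion tibble (`tp`, `fp`, `tn`, `fn`), e.g. from
#'   [aggregate_confusions()].
#' @param normalize Show row percentages instead of raw counts.
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(cm, normalize = TRUE) {
  stopifnot(nrow(cm) == 1)
  df <- tibble::tibble(
    truth = factor(c("SR", "SR", "AF", "AF"), levels = c("SR", "AF")),
    predicted = factor(c("SR", "AF", "SR", "AF"), levels = c("SR", "AF")),
    count = c(cm$tn, cm$fp, cm$fn, cm$tp)
  )
  df <- df |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(text = if (normalize) sprintf("%.1f%%", .data$pct)
                  else as.character(.data$count))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$text)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predicted rhythm", y = "true rhythm", fill = "row %") +
    ggplot2::theme_minimal()
}

#' Plot RR series of cohort subjects
#'
#' Beat-indexed RR tachograms, faceted by subject and coloured by rhythm —
#' the irregularity contrast between AF and sinus rhythm is immediately
#' visible.
#'
#' @param rr_tbl RR tibble (`subject_id`, `rhythm`, `rr_s`).
#' @param subjects How many subjects to show (default 4).
#' @param max_beats Beats plotted per series (default 400).
#' @return A ggplot object.
#' @export
plot_rr_cohort <- function(rr_tbl, subjects = 4, max_beats = 400) {
  ids <- utils::head(unique(rr_tbl$subject_id), subjects)
  df <- rr_tbl |>
    dplyr::filter(.data$subject_id %in% ids) |>
    dplyr::group_by(.data$subject_id, .data$rhythm) |>
    dplyr::slice_head(n = max_beats) |>
    dplyr::mutate(beat = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$beat, .data$rr_s,
                                   colour = .data$rhythm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "beat", y = "RR interval (s)", colour = "rhythm") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
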