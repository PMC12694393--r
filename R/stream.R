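# Desk-scale simulator of the embedded acquire-buffer-infer-publish loop:
# RR intervals and ECG samples accumulate in independent buffers; when the RR
# buffer reaches the window size the classifier runs, an event is emitted and
# both buffers are cleared; AF events become JSON payloads in a pluggable
# sink (a directory of files stands in for the device's MQTT publisher).

#' Create a streaming-inference engine
#'
#' @param model A fitted `rr_cnn` or `rr_cnn_int8`; its window length sets
#'   the RR buffer capacity.
#' @param sink_dir Optional directory receiving one JSON payload file per AF
#'   event (created if needed). `NULL` keeps payloads in memory only.
#' @param fs_hz ECG sampling rate in Hz (default 125).
#' @param stream_id Identifier stamped into payloads.
#' @return An environment of class `"rr_stream_engine"`.
#' @export
rr_stream_engine <- function(model, sink_dir = NULL, fs_hz = 125,
                             stream_id = "stream") {
  stopifnot(inherits(model, "rr_cnn") || inherits(model, "rr_cnn_int8"))
  if (!is.null(sink_dir)) dir.create(sink_dir, recursive = TRUE,
                                     showWarnings = FALSE)
  e <- new.env(parent = emptyenv())
  e$model <- model
  e$capacity <- model$config$n_rr
  e$fs_hz <- fs_hz
  e$sink_dir <- sink_dir
  e$stream_id <- stream_id
  e$rr_buffer <- numeric(0)
  e$ecg_buffer <- numeric(0)
  e$stream_time_s <- 0
  e$inference_index <- 0L
  e$events <- list()
  e$payloads <- list()
  class(e) <- "rr_stream_engine"
  e
}

#' Push one RR interval (and its ECG samples) into the engine
#'
#' Appends the interval and any accompanying ECG chunk to the engine's
#' buffers. When the RR buffer reaches the window size, the model classifies
#' the buffered window, a stream event is emitted, and both buffers are
#' cleared atomically — each RR interval and ECG sample belongs to at most
#' one event.
#'
#' @param engine An [rr_stream_engine()].
#' @param rr_s RR interval in seconds; non-positive values are rejected with
#'   a warning and buffered nothing.
#' @param ecg_chunk Optional numeric vector of ECG samples spanning this
#'   beat-to-beat interval.
#' @return Invisibly `NULL` below capacity, otherwise the emitted event: a
#'   list with `classification` ("SR"/"AF"), `af_probability`,
#'   `inference_index`, `buffer_span_s`, `event_time_s`, `rr_values` and
#'   `ecg_samples`.
#' @export
push_rr <- function(engine, rr_s, ecg_chunk = NULL) {
  stopifnot(inherits(engine, "rr_stream_engine"))
  if (!is.finite(rr_s) || rr_s <= 0) {
    warning("rejected non-positive RR interval: ", rr_s)
    return(invisible(NULL))
  }
  engine$rr_buffer <- c(engine$rr_buffer, rr_s)
  if (!is.null(ecg_chunk)) {
    engine$ecg_buffer <- c(engine$ecg_buffer, ecg_chunk)
  }
  engine$stream_time_s <- engine$stream_time_s + rr_s
  if (length(engine$rr_buffer) < engine$capacity) return(invisible(NULL))

  window <- engine$rr_buffer
  ecg <- engine$ecg_buffer
  engine$rr_buffer <- numeric(0)
  engine$ecg_buffer <- numeric(0)
  engine$inference_index <- engine$inference_index + 1L

  X <- matrix(window, nrow = 1)
  pred <- stats::predict(engine$model, X)
  ev <- list(
    classification = if (pred$.pred_class == 1L) "AF" else "SR",
    af_probability = pred$.pred_AF,
    inference_index = engine$inference_index,
    buffer_span_s = sum(window),
    event_time_s = engine$stream_time_s,
    rr_values = window,
    ecg_samples = ecg
  )
  class(ev) <- "rr_stream_event"
  engine$events[[engine$inference_index]] <- ev
  invisible(ev)
}

#' Handle a stream event: publish AF windows, drop SR windows
#'
#' An AF classification produces a JSON payload carrying the just-cleared
#' window (RR values, aligned ECG samples, sampling rate, AF probability) and
#' delivers it to the engine's sink; a sinus-rhythm classification produces
#' nothing — the buffers were already cleared and acquisition simply
#' continues.
#'
#' @param engine The [rr_stream_engine()] that emitted the event.
#' @param ev An event returned by [push_rr()].
#' @return The payload list (invisibly) for AF events, otherwise `NULL`.
#' @export
handle_event <- function(engine, ev) {
  stopifnot(inherits(ev, "rr_stream_event"))
  if (ev$classification != "AF") return(invisible(NULL))
  payload <- list(
    stream_id = engine$stream_id,
    event_time_s = ev$event_time_s,
    window_length = engine$capacity,
    rr_values = ev$rr_values,
    ecg_samples = ev$ecg_samples,
    sampling_rate_hz = engine$fs_hz,
    af_probability = ev$af_probability
  )
  engine$payloads[[length(engine$payloads) + 1L]] <- payload
  if (!is.null(engine$sink_dir)) {
    path <- file.path(engine$sink_dir,
                      sprintf("af_event_%06d.json", ev$inference_index))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(payload)
}

#' Replay an RR (and optional ECG) stream through the engine
#'
#' Feeds intervals one by one, splitting the ECG trace into per-beat chunks
#' of `round(rr * fs)` samples, and handles every emitted event.
#'
#' @param engine An [rr_stream_engine()].
#' @param rr Numeric RR vector, or a data frame with an `rr_s` column.
#' @param ecg Optional numeric vector of ECG samples at the engine's rate.
#' @return A tibble of events: `inference_index`, `classification`,
#'   `af_probability`, `buffer_span_s`, `event_time_s`, `n_ecg_samples`.
#' @export
stream_rr <- function(engine, rr, ecg = NULL) {
  if (is.data.frame(rr)) rr <- rr$rr_s
  pos <- 0L
  rows <- list()
  for (v in rr) {
    chunk <- NULL
    if (!is.null(ecg)) {
      n_chunk <- round(v * engine$fs_hz)
      hi <- min(pos + n_chunk, length(ecg))
      if (hi > pos) chunk <- ecg[(pos + 1L):hi]
      pos <- hi
    }
    ev <- push_rr(engine, v, chunk)
    if (!is.null(ev)) {
      handle_event(engine, ev)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        inference_index = ev$inference_index,
        classification = ev$classification,
        af_probability = ev$af_probability,
        buffer_span_s = ev$buffer_span_s,
        event_time_s = ev$event_time_s,
        n_ecg_samples = length(ev$ecg_samples)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Fill period of the front-end sample FIFO
#'
#' Time to accumulate `n_samples` ECG samples at `fs_hz`: the cadence of the
#' acquisition interrupt. At 125 Hz a 32-sample FIFO fills every 256 ms
#' (8 ms per sample).
#'
#' @param n_samples FIFO depth in samples (default 32).
#' @param fs_hz Sampling rate in Hz (default 125).
#' @return Period in milliseconds.
#' @export
#' @examples
#' fifo_period() # 256
fifo_period <- function(n_samples = 32, fs_hz = 125) {
  stopifnot(fs_hz > 0)
  n_samples * 1000 / fs_hz
}

#' Mean heart rate of an RR sequence
#'
#' @param rr_values Positive RR intervals in seconds.
#' @return Mean heart rate in beats per minute, rounded to the nearest
#'   integer for display (60 / mean RR).
#' @export
#' @examples
#' mean_hr_bpm(rep(0.767984, 10)) # 78
mean_hr_bpm <- function(rr_values) {
  if (length(rr_values) == 0) stop("empty RR sequence")
  if (any(rr_values <= 0)) stop("RR intervals must be positive")
  round(60 / mean(rr_values))
}
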