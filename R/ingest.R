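#' Record catalogue of the MIT-BIH Atrial Fibrillation Database
#'
#' The 25 long-term Holter records of the PhysioNet `afdb` distribution.
#' Records 00735 and 03665 ship rhythm annotations only, with no ECG signal
#' or beat data, and are therefore unusable for RR extraction.
#'
#' @return A tibble with columns `record` and `has_signal`.
#' @export
afdb_records <- function() {
  no_signal <- c("00735", "03665")
  rec <- c(
    "00735", "03665", "04015", "04043", "04048", "04126", "04746", "04908",
    "04936", "05091", "05121", "05261", "06426", "06453", "06995", "07162",
    "07859", "07879", "07910", "08215", "08219", "08378", "08405", "08434",
    "08455"
  )
  tibble::tibble(record = rec, has_signal = !rec %in% no_signal)
}

#' Keep records usable for RR extraction
#'
#' Filters a record catalogue down to records that carry both rhythm
#' annotations and signal/beat data, preserving order.
#'
#' @param records A data frame with a `record` column and a logical
#'   `has_signal` column (a `has_rhythm` column is honoured when present).
#' @return The filtered tibble.
#' @export
#' @examples
#' usable_records(afdb_records()) # 23 of the 25 afdb records
usable_records <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("record", "has_signal") %in% names(records)))
  keep <- records$has_signal
  if ("has_rhythm" %in% names(records)) keep <- keep & records$has_rhythm
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    stop("no usable records: every record lacks signal or rhythm annotations")
  }
  out
}

#' Turn point rhythm labels into rhythm segments
#'
#' Rhythm annotations are interval-valued: each label marks the rhythm in
#' force from its onset until the next label or the end of the record.
#' Labels map as `"(N"` to sinus rhythm (SR), `"(AFIB"` to atrial
#' fibrillation (AF), and any other label (e.g. `"(AFL"` atrial flutter,
#' `"(J"` junctional rhythm) to OTHER. Labels outside the known vocabulary
#' also map to OTHER, with a warning. Segments are half-open
#' `[start, next_start)`.
#'
#' @param labels A data frame with columns `time_s` (ascending label onsets)
#'   and `label` (rhythm strings such as `"(AFIB"`).
#' @param duration_s Record duration in seconds, closing the last segment.
#' @param subject_id Optional subject identifier carried into the output.
#' @return A tibble with columns `subject_id` (if given), `start_s`, `end_s`
#'   and `rhythm` (`"SR"`, `"AF"` or `"OTHER"`).
#' @export
rhythm_segments <- function(labels, duration_s, subject_id = NULL) {
  stopifnot(is.data.frame(labels), all(c("time_s", "label") %in% names(labels)))
  if (nrow(labels) == 0) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          rhythm = character(0)))
  }
  if (is.unsorted(labels$time_s, strictly = TRUE)) {
    stop("rhythm labels must be strictly ordered in time")
  }
  if (any(labels$time_s >= duration_s)) {
    stop("rhythm label at or beyond the record duration")
  }
  known <- c("(N", "(AFIB", "(AFL", "(J")
  unknown <- setdiff(unique(labels$label), known)
  if (length(unknown) > 0) {
    warning("unknown rhythm label(s) mapped to OTHER: ",
            paste(unknown, collapse = ", "))
  }
  rhythm <- dplyr::case_when(
    labels$label == "(N" ~ "SR",
    labels$label == "(AFIB" ~ "AF",
    TRUE ~ "OTHER"
  )
  out <- tibble::tibble(
    start_s = labels$time_s,
    end_s = c(labels$time_s[-1], duration_s),
    rhythm = rhythm
  )
  if (!is.null(subject_id)) {
    out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
  }
  out
}

#' Extract RR intervals for one rhythm
#'
#' Collects the beats that fall inside segments of the requested rhythm
#' (half-open segments: a beat exactly at a boundary belongs to the later
#' segment), concatenates them in time order, and differences successive beat
#' times to form RR intervals. By default beats of same-rhythm segments are
#' concatenated across intervening other-rhythm segments — the spurious long
#' "interval" spanning a gap is removed later by [filter_rr_range()]. Set
#' `within_segment = TRUE` to difference strictly within each segment instead.
#'
#' @param beats A data frame with a `time_s` column of beat times (seconds),
#'   strictly increasing.
#' @param segments A rhythm-segment tibble from [rhythm_segments()].
#' @param rhythm `"SR"` or `"AF"`.
#' @param within_segment If `TRUE`, never difference across a segment gap.
#' @param subject_id Optional subject identifier carried into the output.
#' @return A tibble with columns `subject_id` (if given), `rhythm` and `rr_s`;
#'   zero rows when fewer than two beats qualify.
#' @export
extract_rr <- function(beats, segments, rhythm = c("SR", "AF"),
                       within_segment = FALSE, subject_id = NULL) {
  rhythm <- match.arg(rhythm)
  stopifnot(is.data.frame(beats), "time_s" %in% names(beats),
            is.data.frame(segments))
  segs <- segments[segments$rhythm == rhythm, , drop = FALSE]
  rr <- numeric(0)
  if (nrow(segs) > 0 && nrow(beats) > 0) {
    t <- sort(beats$time_s)
    seg_of_beat <- rep(NA_integer_, length(t))
    for (k in seq_len(nrow(segs))) {
      inside <- t >= segs$start_s[[k]] & t < segs$end_s[[k]]
      seg_of_beat[inside] <- k
    }
    keep <- !is.na(seg_of_beat)
    t <- t[keep]; seg_of_beat <- seg_of_beat[keep]
    if (length(t) >= 2) {
      d <- diff(t)
      if (within_segment) d <- d[diff(seg_of_beat) == 0]
      rr <- d
    }
  }
  out <- tibble::tibble(rhythm = rep(rhythm, length(rr)), rr_s = rr)
  if (!is.null(subject_id)) {
    out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
  }
  out
}

#' Plausibility-filter RR intervals
#'
#' Keeps RR values inside the closed interval `[lo_s, hi_s]` — by default
#' \code{[0.25, 2]} s, i.e. 30-240 bpm. Values outside typically come from
#' transitions between non-contiguous same-rhythm segments, not real beats.
#'
#' @param rr A data frame with an `rr_s` column.
#' @param lo_s,hi_s Inclusive bounds in seconds (defaults 0.25 and 2.0).
#' @return The filtered tibble, order preserved.
#' @export
#' @examples
#' filter_rr_range(tibble::tibble(rr_s = c(0.8, 0.24, 1.99, 2.01, 150)))
filter_rr_range <- function(rr, lo_s = 0.25, hi_s = 2.0) {
  stopifnot(is.data.frame(rr), "rr_s" %in% names(rr), lo_s < hi_s)
  tibble::as_tibble(rr[rr$rr_s >= lo_s & rr$rr_s <= hi_s, , drop = FALSE])
}

#' Convert an RR interval to heart rate
#'
#' @param rr_s RR interval(s) in seconds; must be positive.
#' @return Heart rate(s) in beats per minute, `60 / rr_s`.
#' @export
#' @examples
#' rr_to_bpm(c(0.25, 2)) # the [0.25, 2] s filter bounds are 240 and 30 bpm
rr_to_bpm <- function(rr_s) {
  if (any(rr_s <= 0)) stop("RR intervals must be positive")
  60 / rr_s
}

#' Read per-rhythm RR series from a WFDB record
#'
#' Reads the record header, beat annotations and rhythm annotations, builds
#' rhythm segments, extracts RR intervals separately for sinus rhythm and AF,
#' and applies the plausibility filter. All annotation symbols in the beat
#' file are treated as beats (Holter beat files are unaudited QRS detections).
#'
#' @param data_dir Directory holding the record files.
#' @param record Record name (e.g. `"04015"`).
#' @param beat_ext Extension of the beat annotation file (default `"qrs"`).
#' @param rhythm_ext Extension of the rhythm annotation file (default
#'   `"atr"`).
#' @param lo_s,hi_s RR plausibility bounds passed to [filter_rr_range()].
#' @param within_segment Passed to [extract_rr()].
#' @return A tibble with columns `subject_id`, `rhythm` and `rr_s`.
#' @export
read_record_rr <- function(data_dir, record, beat_ext = "qrs",
                           rhythm_ext = "atr", lo_s = 0.25, hi_s = 2.0,
                           within_segment = FALSE) {
  hdr <- read_wfdb_header(file.path(data_dir, paste0(record, ".hea")))
  beats <- read_wfdb_annotations(
    file.path(data_dir, paste0(record, ".", beat_ext)), hdr$fs_hz)
  rhy <- read_wfdb_annotations(
    file.path(data_dir, paste0(record, ".", rhythm_ext)), hdr$fs_hz)
  rhy <- rhy[!is.na(rhy$aux) & startsWith(rhy$aux, "("), , drop = FALSE]
  duration <- if (!is.na(hdr$n_samples)) hdr$n_samples / hdr$fs_hz else
    max(beats$time_s, rhy$time_s) + 1
  segs <- rhythm_segments(
    tibble::tibble(time_s = rhy$time_s, label = rhy$aux), duration)
  out <- dplyr::bind_rows(
    extract_rr(beats, segs, "SR", within_segment, subject_id = record),
    extract_rr(beats, segs, "AF", within_segment, subject_id = record)
  )
  filter_rr_range(out, lo_s, hi_s)
}

#' Write per-subject RR series and a manifest
#'
#' Writes one `<subject>_rr.csv` per subject (columns `rr_s`, `rhythm`) plus
#' a `manifest.csv` with per-subject, per-rhythm beat counts and hours.
#'
#' @param rr_tbl A tibble with columns `subject_id`, `rhythm`, `rr_s`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_rr_series <- function(rr_tbl, out_dir) {
  stopifnot(all(c("subject_id", "rhythm", "rr_s") %in% names(rr_tbl)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(rr_tbl$subject_id)) {
    sub <- rr_tbl[rr_tbl$subject_id == sid, c("rr_s", "rhythm")]
    readr::write_csv(sub, file.path(out_dir, paste0(sid, "_rr.csv")))
  }
  manifest <- rr_tbl |>
    dplyr::group_by(.data$subject_id, .data$rhythm) |>
    dplyr::summarise(n_rr = dplyr::n(),
                     hours = sum(.data$rr_s) / 3600, .groups = "drop")
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Read RR series written by [write_rr_series()]
#'
#' @param dir Directory of `*_rr.csv` files.
#' @return A tibble with columns `subject_id`, `rhythm`, `rr_s`.
#' @export
read_rr_series <- function(dir) {
  files <- list.files(dir, pattern = "_rr\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no *_rr.csv files in ", dir)
  purrr::map(files, function(f) {
    x <- readr::read_csv(f, show_col_types = FALSE)
    tibble::tibble(subject_id = sub("_rr\\.csv$", "", basename(f)),
                   rhythm = x$rhythm, rr_s = x$rr_s)
  }) |> dplyr::bind_rows()
}
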