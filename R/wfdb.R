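# Minimal reader/writer for the MIT annotation format and .hea headers.
# The annotation stream is a sequence of 16-bit little-endian words:
# top 6 bits = annotation type code, low 10 bits = sample-interval increment.
# Pseudo-annotation codes: SKIP(59) carries a 4-byte interval (high word
# first), NUM(60)/SUB(61)/CHN(62) modify bookkeeping fields, AUX(63) is
# followed by its byte count of auxiliary text padded to even length.
# A zero word terminates the stream.

.ann_symbols <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

.SKIP <- 59L; .NUM <- 60L; .SUB <- 61L; .CHN <- 62L; .AUX <- 63L

#' Read a WFDB record header (.hea)
#'
#' Parses the first line of a WFDB header file: record name, number of
#' signals, sampling frequency and number of samples. Signal specification
#' lines are not interpreted.
#'
#' @param path Path to a `.hea` file.
#' @return A list with `record`, `n_sig`, `fs_hz` and `n_samples`
#'   (`n_samples` may be `NA` when the header omits it).
#' @export
read_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty WFDB header: ", path)
  f <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  fs <- if (length(f) >= 3) as.numeric(sub("/.*$", "", f[[3]])) else 250
  list(
    record = sub("/.*$", "", f[[1]]),
    n_sig = as.integer(f[[2]]),
    fs_hz = fs,
    n_samples = if (length(f) >= 4) as.numeric(f[[4]]) else NA_real_
  )
}

#' Read a WFDB annotation file
#'
#' Decodes a MIT-format annotation stream (e.g. `.atr` rhythm/beat
#' annotations or `.qrs` beat detections) into a tibble. Auxiliary strings —
#' which carry rhythm labels such as `"(N"` and `"(AFIB"` on `+` annotations —
#' are attached to the annotation they follow.
#'
#' @param path Path to the annotation file.
#' @param fs_hz Sampling frequency used to convert sample indices to seconds.
#' @return A tibble with columns `sample` (integer sample index), `time_s`,
#'   `code` (integer annotation type), `symbol` (display character) and
#'   `aux` (auxiliary string or `NA`).
#' @export
read_wfdb_annotations <- function(path, fs_hz) {
  stopifnot(fs_hz > 0)
  raw <- readBin(path, "raw", n = file.size(path))
  n_words <- length(raw) %/% 2L
  sample <- integer(0); code <- integer(0); aux <- character(0)
  cur_sample <- 0
  i <- 1L
  while (i <= n_words) {
    lo <- as.integer(raw[2L * i - 1L]); hi <- as.integer(raw[2L * i])
    word <- lo + 256L * hi
    typ <- word %/% 1024L
    interval <- word %% 1024L
    i <- i + 1L
    if (word == 0L) break
    if (typ == .SKIP) {
      # 4-byte interval follows: high 16 bits then low 16 bits
      hi16 <- as.integer(raw[2L * i - 1L]) + 256L * as.integer(raw[2L * i])
      lo16 <- as.integer(raw[2L * i + 1L]) + 256L * as.integer(raw[2L * i + 2L])
      i <- i + 2L
      long_int <- hi16 * 65536 + lo16
      if (long_int >= 2^31) long_int <- long_int - 2^32
      cur_sample <- cur_sample + long_int
    } else if (typ == .AUX) {
      n_bytes <- interval
      start <- 2L * (i - 1L) + 1L
      bytes <- raw[start:(start + n_bytes - 1L)]
      txt <- rawToChar(bytes[bytes != as.raw(0)])
      if (length(code) > 0) aux[length(code)] <- txt
      i <- i + as.integer(ceiling(n_bytes / 2))
    } else if (typ %in% c(.NUM, .SUB, .CHN)) {
      # bookkeeping fields; not retained
    } else {
      cur_sample <- cur_sample + interval
      sample <- c(sample, cur_sample)
      code <- c(code, typ)
      aux <- c(aux, NA_character_)
    }
  }
  tibble::tibble(
    sample = as.integer(sample),
    time_s = sample / fs_hz,
    code = code,
    symbol = unname(.ann_symbols[as.character(code)]),
    aux = aux
  )
}

#' Write a WFDB annotation file
#'
#' Emits a MIT-format annotation stream from a tibble of annotations, the
#' inverse of [read_wfdb_annotations()]. Useful for constructing playback
#' benches and test records without external data.
#'
#' @param ann A data frame with columns `sample`, `code` and optionally `aux`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(ann, path) {
  stopifnot(all(c("sample", "code") %in% names(ann)))
  ann <- ann[order(ann$sample), , drop = FALSE]
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(w) {
    writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  }
  prev <- 0
  for (k in seq_len(nrow(ann))) {
    delta <- ann$sample[[k]] - prev
    prev <- ann$sample[[k]]
    if (delta > 1023) {
      put_word(.SKIP * 1024L)
      put_word(delta %/% 65536)         # high 16 bits
      put_word(delta %% 65536)          # low 16 bits
      delta <- 0
    }
    put_word(ann$code[[k]] * 1024L + delta)
    aux <- if ("aux" %in% names(ann)) ann$aux[[k]] else NA_character_
    if (!is.na(aux) && nzchar(aux)) {
      bytes <- charToRaw(aux)
      if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0))
      put_word(.AUX * 1024L + length(charToRaw(aux)))
      writeBin(bytes, con)
    }
  }
  put_word(0L)
  invisible(path)
}
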