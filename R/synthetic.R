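#' Simulate a sinus-rhythm RR-interval series
#'
#' Sinus rhythm is modelled as a subject-specific mean RR interval modulated by
#' a slow sinusoid standing in for respiratory sinus arrhythmia (RSA), plus
#' small Gaussian beat-to-beat noise:
#' \deqn{RR_i = \mu + A \sin(2\pi t_i / T) + \epsilon_i, \quad
#'       \epsilon_i \sim N(0, \sigma^2)}
#' where \eqn{t_i} is the cumulative beat time. Values are clipped to
#' \code{[0.3, 1.8]} s so simulated beats always survive the downstream
#' \code{[0.25, 2]} s plausibility filter.
#'
#' @param n_beats Number of RR intervals to generate.
#' @param mean_rr_s Subject mean RR interval in seconds. Default: one draw from
#'   Uniform(0.7, 1.0), the typical resting sinus range (60-86 bpm).
#' @param rsa_amplitude_s RSA modulation amplitude in seconds (default 0.04).
#' @param rsa_period_s RSA modulation period in seconds (default 4.5,
#'   a typical respiratory cycle).
#' @param noise_sd_s Beat-to-beat Gaussian noise SD in seconds (default 0.02).
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return Numeric vector of \code{n_beats} RR intervals in seconds.
#' @seealso [simulate_af_rr()], [simulate_rr_cohort()]
#' @export
#' @examples
#' rr <- simulate_sr_rr(200, seed = 1)
#' sd(rr) / mean(rr) # coefficient of variation well below AF levels
simulate_sr_rr <- function(n_beats,
                           mean_rr_s = NULL,
                           rsa_amplitude_s = 0.04,
                           rsa_period_s = 4.5,
                           noise_sd_s = 0.02,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_rr_s)) mean_rr_s <- stats::runif(1, 0.7, 1.0)
  stopifnot(n_beats >= 0, mean_rr_s > 0, rsa_period_s > 0)
  if (n_beats == 0) return(numeric(0))
  rr <- numeric(n_beats)
  t_i <- 0
  eps <- stats::rnorm(n_beats, 0, noise_sd_s)
  for (i in seq_len(n_beats)) {
    rr[i] <- mean_rr_s +
      rsa_amplitude_s * sin(2 * pi * t_i / rsa_period_s) + eps[i]
    rr[i] <- min(max(rr[i], 0.3), 1.8)
    t_i <- t_i + rr[i]
  }
  rr
}

#' Simulate an atrial-fibrillation RR-interval series
#'
#' During AF the ventricular response is irregularly irregular: successive RR
#' intervals are highly variable and carry almost no serial correlation. That
#' single property — irregularity — is what the RR-window classifier exploits,
#' so AF is modelled as i.i.d. Gamma draws with a target coefficient of
#' variation (CV), clipped to \code{[0.3, 1.8]} s. The Gamma shape is
#' \eqn{1/\mathrm{CV}^2} and the scale \eqn{\mu \cdot \mathrm{CV}^2}. This is a
#' statistical stand-in, not a physiological AV-node model.
#'
#' @param n_beats Number of RR intervals to generate.
#' @param mean_rr_s Mean RR in seconds. Default: one draw from
#'   Uniform(0.55, 0.85) (AF typically runs faster than sinus rhythm).
#' @param cv Coefficient of variation of the RR intervals (default 0.22,
#'   in the range reported for AF ventricular response).
#' @param seed Optional integer seed.
#' @return Numeric vector of \code{n_beats} RR intervals in seconds.
#' @seealso [simulate_sr_rr()], [simulate_rr_cohort()]
#' @export
simulate_af_rr <- function(n_beats,
                           mean_rr_s = NULL,
                           cv = 0.22,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_rr_s)) mean_rr_s <- stats::runif(1, 0.55, 0.85)
  stopifnot(n_beats >= 0, mean_rr_s > 0, cv >= 0)
  if (n_beats == 0) return(numeric(0))
  if (cv == 0) return(rep(mean_rr_s, n_beats))
  shape <- 1 / cv^2
  rr <- stats::rgamma(n_beats, shape = shape, scale = mean_rr_s / shape)
  pmin(pmax(rr, 0.3), 1.8)
}

#' Simulate a cohort of subjects with sinus-rhythm and AF recordings
#'
#' Generates per-subject RR streams for both rhythms in the long layout the
#' ingest stage emits, mirroring the structure of a rhythm-annotated Holter
#' cohort: each subject contributes a sinus-rhythm series and an AF series,
#' with the AF share of total recording time near `af_time_fraction`.
#' Per-subject means are drawn once per subject; all draws derive from `seed`,
#' so the cohort is fully reproducible.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param beats_per_subject Total beats per subject across both rhythms
#'   (default 5000, keeping a full-pipeline run desk-scale).
#' @param af_time_fraction Target fraction of recorded time spent in AF
#'   (default 0.45, matching an AF-screening database where roughly 91 of
#'   204 hours are AF).
#' @param seed Integer seed for the whole cohort.
#' @return A tibble with columns `subject_id`, `rhythm` ("SR"/"AF") and `rr_s`,
#'   ordered by subject, rhythm and beat. The per-subject generative
#'   parameters are attached as the `"profiles"` attribute (a tibble).
#' @export
#' @examples
#' cohort <- simulate_rr_cohort(n_subjects = 4, beats_per_subject = 500, seed = 1)
#' dplyr::count(cohort, subject_id, rhythm)
simulate_rr_cohort <- function(n_subjects = 23,
                               beats_per_subject = 5000,
                               af_time_fraction = 0.45,
                               seed = 1L) {
  stopifnot(n_subjects >= 1, beats_per_subject >= 2,
            af_time_fraction >= 0, af_time_fraction <= 1)
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  profiles <- tibble::tibble(
    subject_id = ids,
    sr_mean_rr_s = stats::runif(n_subjects, 0.7, 1.0),
    af_mean_rr_s = stats::runif(n_subjects, 0.55, 0.85),
    af_cv = rep(0.22, n_subjects),
    sr_noise_sd_s = rep(0.02, n_subjects),
    rsa_amplitude_s = rep(0.04, n_subjects),
    rsa_period_s = rep(4.5, n_subjects),
    subject_seed = sample.int(.Machine$integer.max, n_subjects)
  )
  # beats split so that AF time / total time hits the target fraction
  f <- af_time_fraction
  n_af <- round(f * beats_per_subject * profiles$sr_mean_rr_s /
                  (profiles$af_mean_rr_s * (1 - f) + f * profiles$sr_mean_rr_s))
  n_af <- pmin(pmax(n_af, 0L), beats_per_subject)
  profiles$n_af_beats <- as.integer(n_af)
  profiles$n_sr_beats <- as.integer(beats_per_subject - n_af)

  out <- purrr::pmap(profiles, function(subject_id, sr_mean_rr_s, af_mean_rr_s,
                                        af_cv, sr_noise_sd_s, rsa_amplitude_s,
                                        rsa_period_s, subject_seed,
                                        n_af_beats, n_sr_beats) {
    sr <- simulate_sr_rr(n_sr_beats, mean_rr_s = sr_mean_rr_s,
                         rsa_amplitude_s = rsa_amplitude_s,
                         rsa_period_s = rsa_period_s,
                         noise_sd_s = sr_noise_sd_s, seed = subject_seed)
    af <- simulate_af_rr(n_af_beats, mean_rr_s = af_mean_rr_s, cv = af_cv,
                         seed = subject_seed + 1L)
    tibble::tibble(
      subject_id = subject_id,
      rhythm = rep(c("SR", "AF"), c(length(sr), length(af))),
      rr_s = c(sr, af)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "profiles") <- profiles
  attr(out, "seed") <- seed
  out
}

#' Synthesize an ECG-like trace from RR intervals
#'
#' Places a stereotyped QRS-like deflection (narrow positive Gaussian, ~1 mV
#' peak, ~40 ms width) at each cumulative beat time and adds a low-amplitude
#' smooth baseline wander, sampled at `fs_hz`. The morphology is deliberately
#' minimal: it supports buffer-alignment and playback-bench tests, not
#' waveform-level analysis (no P waves, no fibrillatory waves).
#'
#' @param rr_values Numeric vector of RR intervals in seconds (each in
#'   \code{[0.25, 2]}).
#' @param fs_hz Sampling rate in Hz (default 125, the front-end's ECG rate).
#' @return A tibble with columns `time_s` and `ecg_mv`; the beat times are
#'   attached as the `"beat_times_s"` attribute.
#' @export
simulate_ecg <- function(rr_values, fs_hz = 125) {
  stopifnot(fs_hz > 0)
  if (length(rr_values) == 0) {
    out <- tibble::tibble(time_s = numeric(0), ecg_mv = numeric(0))
    attr(out, "beat_times_s") <- numeric(0)
    return(out)
  }
  stopifnot(all(rr_values >= 0.25), all(rr_values <= 2))
  beat_times <- cumsum(rr_values)
  duration <- beat_times[length(beat_times)]
  n <- ceiling(duration * fs_hz - 1e-9) # guard float fuzz at exact multiples
  t <- (seq_len(n) - 1) / fs_hz
  qrs_sd <- 0.040 / 4 # ~40 ms full width at ~2 sd each side
  ecg <- 0.05 * sin(2 * pi * t / 3.7) # slow baseline wander, 0.05 mV
  for (bt in beat_times) {
    idx <- which(abs(t - bt) < 6 * qrs_sd)
    ecg[idx] <- ecg[idx] + 1.0 * exp(-((t[idx] - bt)^2) / (2 * qrs_sd^2))
  }
  out <- tibble::tibble(time_s = t, ecg_mv = ecg)
  attr(out, "beat_times_s") <- beat_times
  out
}

#' Quantize a millivolt signal through an ideal DAC
#'
#' Models the playback bench that drives an analog front-end from stored ECG:
#' the signal, rescaled into \code{[0, vref_v]} volts, is truncated to
#' `bits`-bit codes. The step size is \eqn{LSB = 1000 \cdot V_{ref} / 2^{bits}}
#' millivolts — 3.3 V at 12 bits gives the familiar 0.805 mV per step.
#'
#' @param signal_mv Numeric signal in millivolts, already scaled to lie within
#'   \code{[0, 1000 * vref_v]}.
#' @param vref_v DAC reference voltage in volts (default 3.3).
#' @param bits DAC resolution in bits (default 12).
#' @return A list with `codes` (integer DAC codes in
#'   \code{[0, 2^bits - 1]}), `lsb_mv` (step size in millivolts) and
#'   `reconstructed_mv` (codes mapped back to millivolts; within one LSB of
#'   the input).
#' @export
#' @examples
#' quantize_to_dac(c(0, 1650, 3300))$lsb_mv # ~0.806 mV per step
quantize_to_dac <- function(signal_mv, vref_v = 3.3, bits = 12) {
  stopifnot(bits >= 1, vref_v > 0)
  lsb_mv <- 1000 * vref_v / 2^bits
  codes <- floor(signal_mv / lsb_mv)
  codes <- pmin(pmax(codes, 0), 2^bits - 1)
  list(codes = as.integer(codes),
       lsb_mv = lsb_mv,
       reconstructed_mv = codes * lsb_mv)
}
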