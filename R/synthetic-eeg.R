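#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the two-class structure the classifier assumes:
#' the interictal (between-seizure) state is broadband background noise, and
#' the ictal (seizure) state adds a higher-amplitude rhythmic burst on every
#' channel. The burst amplitude is
#' `background_noise_sd * (ictal_amplitude_gain - 1)`, so a gain of exactly 1
#' removes the burst and the two classes share one generative law, while any
#' gain above 1 makes them separable in expectation by amplitude/band power.
#'
#' @param sampling_rate_hz Sampling rate (default 256 Hz).
#' @param n_channels Number of channels (default 23).
#' @param segment_seconds Segment length in seconds, one of 1, 2, 4.
#' @param n_segments_per_class Segments to generate per class.
#' @param ictal_burst_freq_hz Frequency of the rhythmic ictal burst (default
#'   4 Hz, the spike-wave band of many generalized seizures).
#' @param ictal_amplitude_gain Amplitude gain of the ictal state relative to
#'   background; must exceed 1 for separable classes (default 3).
#' @param background_noise_sd Standard deviation of the background noise in
#'   arbitrary signal units (default 1; scale is removed downstream by
#'   normalization).
#' @param pink_background Colour the background as 1/f ("pink") noise rather
#'   than white noise.
#' @param seed Integer seed; identical configurations with identical seeds
#'   yield bit-identical data.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 256, n_channels = 23,
                         segment_seconds = 2, n_segments_per_class = 10,
                         ictal_burst_freq_hz = 4.0, ictal_amplitude_gain = 3.0,
                         background_noise_sd = 1.0, pink_background = FALSE,
                         seed = 1) {
  stopifnot(sampling_rate_hz > 0, n_channels >= 1,
            segment_seconds %in% c(1, 2, 4), n_segments_per_class >= 1,
            ictal_burst_freq_hz > 0, ictal_amplitude_gain >= 1,
            background_noise_sd > 0)
  rows <- sampling_rate_hz * segment_seconds
  if (abs(rows - round(rows)) > 1e-9)
    stop("sampling_rate_hz * segment_seconds must be an integer")
  structure(list(
    sampling_rate_hz = sampling_rate_hz, n_channels = n_channels,
    segment_seconds = segment_seconds,
    n_segments_per_class = n_segments_per_class,
    ictal_burst_freq_hz = ictal_burst_freq_hz,
    ictal_amplitude_gain = ictal_amplitude_gain,
    background_noise_sd = background_noise_sd,
    pink_background = pink_background, seed = as.integer(seed)
  ), class = "synth_config")
}

noise_matrix <- function(n, m, sd, pink) {
  if (!pink) return(matrix(rnorm(n * m, sd = sd), n, m))
  # 1/f colouring: shape the spectrum of white noise, rescale to sd
  out <- matrix(0, n, m)
  f <- c(1, seq_len(n - 1))
  scale <- 1 / sqrt(pmin(f, n - f + 1))
  for (j in seq_len(m)) {
    z <- stats::fft(rnorm(n))
    x <- Re(stats::fft(z * scale, inverse = TRUE)) / n
    out[, j] <- x / stats::sd(x) * sd
  }
  out
}

# One segment (rows = time, cols = channels); ictal segments add a sinusoidal
# burst with an independent random phase per channel.
synth_segment <- function(config, ictal) {
  rows <- as.integer(config$sampling_rate_hz * config$segment_seconds)
  x <- noise_matrix(rows, config$n_channels, config$background_noise_sd,
                    config$pink_background)
  if (ictal) {
    amp <- config$background_noise_sd * (config$ictal_amplitude_gain - 1)
    if (amp > 0) {
      tt <- (seq_len(rows) - 1) / config$sampling_rate_hz
      phase <- runif(config$n_channels, 0, 2 * pi)
      x <- x + amp * sin(outer(2 * pi * config$ictal_burst_freq_hz * tt,
                               phase, `+`))
    }
  }
  x
}

#' Generate a labelled collection of EEG segments
#'
#' Produces `n_segments_per_class` ictal and as many interictal segments,
#' each an `(I x J)` matrix with `I = sampling_rate_hz * segment_seconds`
#' rows and `J = n_channels` columns. Ictal segments come first.
#'
#' @param config A [synth_config()].
#' @return Object of class `eeg_segments`: list with `x` (array
#'   `(2n, I, J)`), `labels` (1 = ictal, 0 = interictal) and `config`.
#' @export
#' @examples
#' seg <- generate_segments(synth_config(n_segments_per_class = 5))
#' dim(seg$x)  # 10 x 512 x 23
generate_segments <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- as.integer(config$sampling_rate_hz * config$segment_seconds)
  n <- config$n_segments_per_class
  with_seed(config$seed, {
    x <- array(0, c(2L * n, rows, config$n_channels))
    for (i in seq_len(n)) x[i, , ] <- synth_segment(config, TRUE)
    for (i in seq_len(n)) x[n + i, , ] <- synth_segment(config, FALSE)
    structure(list(x = x, labels = rep(c(1L, 0L), each = n), config = config),
              class = "eeg_segments")
  })
}

#' Generate a continuous annotated EEG recording
#'
#' Builds a recording of `duration_s` seconds with `n_seizures` annotated
#' seizure intervals, each at least 10 s long (shorter events are excluded
#' from analysis and therefore never generated), placed uniformly at random
#' without overlap. Inside the intervals the signal follows the ictal law of
#' [generate_segments()]; elsewhere it is pure background.
#'
#' @param config A [synth_config()].
#' @param duration_s Recording duration in seconds (integer).
#' @param n_seizures Number of seizure intervals.
#' @param min_seizure_s,max_seizure_s Bounds on seizure duration (seconds).
#' @return Object of class `eeg_recording`: list with `values`
#'   (channels x samples matrix), `sampling_rate_hz`, `channel_names` and
#'   `seizure_intervals` (matrix with `start_s`, `end_s` columns; half-open
#'   `[start, end)` seconds, sorted, non-overlapping).
#' @export
generate_recording <- function(config, duration_s, n_seizures,
                               min_seizure_s = 10, max_seizure_s = 30) {
  stopifnot(inherits(config, "synth_config"), duration_s > 0, n_seizures >= 0,
            min_seizure_s >= 10, max_seizure_s >= min_seizure_s)
  with_seed(config$seed + 1L, {
    lens <- if (n_seizures > 0)
      round(runif(n_seizures, min_seizure_s, max_seizure_s)) else numeric(0)
    free <- duration_s - sum(lens)
    if (free < 0)
      stop(sprintf(
        "cannot place %d seizures of >= %g s in a %g-s recording",
        n_seizures, min_seizure_s, duration_s))
    # split the free time into n+1 gaps via a sorted uniform draw
    cuts <- sort(runif(n_seizures, 0, free))
    starts <- cuts + c(0, cumsum(lens))[seq_len(n_seizures)]
    intervals <- cbind(start_s = round(starts), end_s = round(starts) + lens)
    n_samp <- as.integer(round(duration_s * config$sampling_rate_hz))
    values <- t(noise_matrix(n_samp, config$n_channels,
                             config$background_noise_sd,
                             config$pink_background))
    amp <- config$background_noise_sd * (config$ictal_amplitude_gain - 1)
    if (n_seizures > 0 && amp > 0) {
      tt <- (seq_len(n_samp) - 1) / config$sampling_rate_hz
      for (i in seq_len(n_seizures)) {
        idx <- which(tt >= intervals[i, 1] & tt < intervals[i, 2])
        phase <- runif(config$n_channels, 0, 2 * pi)
        burst <- amp * sin(outer(phase,
                                 2 * pi * config$ictal_burst_freq_hz * tt[idx],
                                 `+`))
        values[, idx] <- values[, idx] + burst
      }
    }
    structure(list(
      values = values, sampling_rate_hz = config$sampling_rate_hz,
      channel_names = default_channel_names(config$n_channels),
      seizure_intervals = intervals
    ), class = "eeg_recording")
  })
}

# 10-20-style channel labels for synthetic montages (bipolar-like naming).
default_channel_names <- function(n) {
  base <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3",
            "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8", "F8-T8",
            "T8-P8", "P8-O2", "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9", "FT9-FT10",
            "FT10-T8", "T8-P8b")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("CH%02d", seq_len(n - length(base))))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d seizure(s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate_hz,
              nrow(x$seizure_intervals %||% matrix(0, 0, 2))))
  invisible(x)
}

#' @export
print.eeg_segments <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<eeg_segments> %d segments (%d ictal / %d interictal), %d x %d\n",
              d[1], sum(x$labels == 1), sum(x$labels == 0), d[2], d[3]))
  invisible(x)
}
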