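# Minimal EDF (European Data Format) support: enough to round-trip
# fixed-rate multichannel recordings with 1-second data records. Values are
# stored as 16-bit little-endian integers with per-channel physical scaling,
# so a write/read round trip is exact up to the format's quantization step
# (physical range / 65535).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

num_field <- function(x, width = 8) pad_field(formatC(x, format = "g", digits = 6), width)

#' Write a recording to an EDF file
#'
#' Uses 1-second data records and a 16-bit digital range of -32768..32767 with
#' per-channel physical min/max taken from the data (rounded to 6 significant
#' digits and applied consistently, so the only round-trip error is the
#' quantization step). The recording duration must be a whole number of
#' seconds and the sampling rate an integer.
#'
#' @param recording An `eeg_recording` (values as channels x samples), e.g.
#'   from [generate_recording()].
#' @param path Output file path.
#' @param patient_id,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient_id = "X",
                      recording_id = "synthetic") {
  values <- recording$values
  fs <- recording$sampling_rate_hz
  stopifnot(is.matrix(values), fs == round(fs))
  ns <- nrow(values)
  n_samp <- ncol(values)
  if (n_samp %% fs != 0)
    stop("recording length must be a whole number of seconds")
  n_rec <- n_samp %/% fs
  labels <- recording$channel_names %||% default_channel_names(ns)

  pmin_ <- apply(values, 1, min)
  pmax_ <- apply(values, 1, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  pmin_ <- signif(pmin_, 6)
  pmax_ <- signif(pmax_, 6)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field(patient_id, 80))
  wr(pad_field(recording_id, 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(256 + ns * 256, 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))
  wr(pad_field(ns, 4))
  for (l in labels) wr(pad_field(l, 16))
  for (i in seq_len(ns)) wr(pad_field("", 80))       # transducer
  for (i in seq_len(ns)) wr(pad_field("uV", 8))      # dimension
  for (i in seq_len(ns)) wr(num_field(pmin_[i]))
  for (i in seq_len(ns)) wr(num_field(pmax_[i]))
  for (i in seq_len(ns)) wr(pad_field(dmin, 8))
  for (i in seq_len(ns)) wr(pad_field(dmax, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))       # prefiltering
  for (i in seq_len(ns)) wr(pad_field(fs, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((values[i, idx] - pmin_[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path Path to an EDF file with a fixed number of samples per record
#'   across one-second data records.
#' @return An `eeg_recording` (without seizure annotations; see
#'   [read_annotations()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  values <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      values[i, idx] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  structure(list(values = values, sampling_rate_hz = fs,
                 channel_names = labels, seizure_intervals = NULL),
            class = "eeg_recording")
}

#' Write seizure annotations as a plain-text sidecar
#'
#' One interval per line: `start_s end_s` (seconds, half-open `[start, end)`).
#'
#' @param intervals Matrix with start/end columns (seconds).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(intervals, path) {
  intervals <- as_intervals(intervals)
  write.table(intervals, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a seizure annotation sidecar
#'
#' @param path Path to a file written by [write_annotations()].
#' @return Matrix with `start_s` and `end_s` columns (possibly 0 rows).
#' @export
read_annotations <- function(path) {
  if (file.size(path) == 0) return(as_intervals(matrix(0, 0, 2)))
  as_intervals(as.matrix(read.table(path, col.names = c("start_s", "end_s"))))
}

as_intervals <- function(x) {
  if (is.null(x)) x <- matrix(0, 0, 2)
  if (!is.matrix(x)) x <- matrix(unlist(x), ncol = 2, byrow = TRUE)
  storage.mode(x) <- "double"
  colnames(x) <- c("start_s", "end_s")
  if (nrow(x) > 1) {
    if (is.unsorted(x[, 1])) stop("intervals must be sorted by start time")
    if (any(x[-1, 1] < x[-nrow(x), 2])) stop("intervals must not overlap")
  }
  if (any(x[, 2] < x[, 1])) stop("interval end before start")
  x
}

#' Manifest describing one EDF recording and its annotations
#'
#' Channel identity is enforced through the manifest, not taken from file
#' order: recordings whose montages drift (renamed channels, re-placed
#' electrodes) surface as explicit channel-not-found errors instead of
#' silently misaligned data.
#'
#' @param record_id Identifier string (e.g. `"chb01_03"`).
#' @param edf_path Path to the EDF file.
#' @param channel_names Ordered channel selection (default: the standard
#'   23-channel bipolar montage naming).
#' @param annotation_path Optional path to a [write_annotations()] sidecar.
#' @param sampling_rate_hz Expected sampling rate (default 256).
#' @return Object of class `recording_manifest`.
#' @export
recording_manifest <- function(record_id, edf_path,
                               channel_names = default_channel_names(23),
                               annotation_path = NULL,
                               sampling_rate_hz = 256) {
  structure(list(record_id = record_id, edf_path = edf_path,
                 channel_names = channel_names,
                 annotation_path = annotation_path,
                 sampling_rate_hz = sampling_rate_hz),
            class = "recording_manifest")
}

#' Read a recording through its manifest
#'
#' Reads the EDF file, checks the sampling rate, selects and orders channels
#' as listed in the manifest, and attaches the annotation sidecar's seizure
#' intervals when present.
#'
#' @param manifest A [recording_manifest()].
#' @return An `eeg_recording` with channels in manifest order.
#' @export
read_recording <- function(manifest) {
  stopifnot(inherits(manifest, "recording_manifest"))
  if (!file.exists(manifest$edf_path))
    stop("EDF file not found: ", manifest$edf_path)
  rec <- read_edf(manifest$edf_path)
  if (abs(rec$sampling_rate_hz - manifest$sampling_rate_hz) > 1e-9)
    stop(sprintf("sampling rate mismatch: file has %g Hz, manifest expects %g Hz",
                 rec$sampling_rate_hz, manifest$sampling_rate_hz))
  pos <- match(manifest$channel_names, rec$channel_names)
  if (anyNA(pos))
    stop("channel(s) not found in EDF file: ",
         paste(manifest$channel_names[is.na(pos)], collapse = ", "))
  rec$values <- rec$values[pos, , drop = FALSE]
  rec$channel_names <- manifest$channel_names
  if (!is.null(manifest$annotation_path))
    rec$seizure_intervals <- read_annotations(manifest$annotation_path)
  rec
}

#' Drop seizures shorter than a minimum duration
#'
#' Events shorter than `min_duration_s` (default 10 s) are excluded from
#' analysis; interval endpoints are never edited and order is preserved.
#'
#' @param intervals Interval matrix (start/end seconds), sorted,
#'   non-overlapping.
#' @param min_duration_s Minimum retained duration in seconds.
#' @return The qualifying subset of `intervals`.
#' @export
#' @examples
#' filter_seizures(rbind(c(0, 8), c(100, 130)))  # keeps only (100, 130)
filter_seizures <- function(intervals, min_duration_s = 10) {
  intervals <- as_intervals(intervals)
  intervals[intervals[, 2] - intervals[, 1] >= min_duration_s, , drop = FALSE]
}
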