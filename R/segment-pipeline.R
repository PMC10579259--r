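#' Cut non-overlapping segments out of a recording
#'
#' Segments are cut left-aligned, contiguously and without overlap inside
#' each qualifying region; trailing partial windows are discarded. For
#' `state = "ictal"` the qualifying regions are the seizure intervals
#' themselves; for `state = "interictal"` they are the parts of the recording
#' outside the seizure intervals enlarged by an exclusion buffer (default
#' 30 minutes, mirroring the conventional preictal window), so that
#' peri-seizure data contaminates neither class. Ictal and interictal segment
#' sets are therefore disjoint in recording time.
#'
#' @param recording An `eeg_recording`.
#' @param intervals Seizure intervals (start/end seconds); defaults to the
#'   recording's own annotations.
#' @param segment_seconds Segment length, one of 1, 2, 4.
#' @param state `"ictal"` or `"interictal"`.
#' @param buffer_s Exclusion buffer around each seizure for interictal
#'   extraction, in seconds (default 1800).
#' @param record_id Identifier recorded in the provenance manifest.
#' @return List with `x` (array `(n, I, J)`, possibly `n = 0`), `labels`,
#'   and `provenance` (data frame with the record id, source region and
#'   within-recording offset of every segment; see
#'   [write_segment_manifest()]).
#' @export
extract_segments <- function(recording, intervals = NULL,
                             segment_seconds = 4,
                             state = c("ictal", "interictal"),
                             buffer_s = 1800, record_id = "recording") {
  state <- match.arg(state)
  stopifnot(inherits(recording, "eeg_recording"),
            segment_seconds %in% c(1, 2, 4))
  intervals <- as_intervals(intervals %||% recording$seizure_intervals)
  fs <- recording$sampling_rate_hz
  dur <- ncol(recording$values) / fs
  regions <- if (state == "ictal") {
    intervals
  } else {
    complement_intervals(cbind(pmax(0, intervals[, 1] - buffer_s),
                               pmin(dur, intervals[, 2] + buffer_s)), dur)
  }
  seg_len <- as.integer(round(segment_seconds * fs))
  rows <- list()
  prov <- list()
  for (i in seq_len(nrow(regions))) {
    s0 <- as.integer(ceiling(regions[i, 1] * fs))   # 0-based sample index
    s1 <- as.integer(floor(regions[i, 2] * fs))
    n_seg <- max(0, (s1 - s0) %/% seg_len)
    for (k in seq_len(n_seg)) {
      a <- s0 + (k - 1L) * seg_len
      rows[[length(rows) + 1L]] <-
        t(recording$values[, (a + 1L):(a + seg_len), drop = FALSE])
      prov[[length(prov) + 1L]] <- data.frame(
        record_id = record_id, state = state, region = i,
        region_start_s = regions[i, 1], region_end_s = regions[i, 2],
        offset_s = a / fs, stringsAsFactors = FALSE)
    }
  }
  n <- length(rows)
  x <- array(0, c(n, seg_len, nrow(recording$values)))
  for (i in seq_len(n)) x[i, , ] <- rows[[i]]
  list(x = x, labels = rep(if (state == "ictal") 1L else 0L, n),
       provenance = if (n > 0) do.call(rbind, prov) else
         data.frame(record_id = character(0), state = character(0),
                    region = integer(0), region_start_s = numeric(0),
                    region_end_s = numeric(0), offset_s = numeric(0)))
}

#' Write a CSV manifest of segment provenance
#'
#' Records where every extracted segment came from (record id, source
#' region, within-recording offset), so prepared datasets remain traceable
#' to recording time.
#'
#' @param provenance The `provenance` data frame from [extract_segments()]
#'   (or several of them bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_manifest <- function(provenance, path) {
  utils::write.csv(provenance, path, row.names = FALSE)
  invisible(path)
}

# Complement of a union of (possibly merged) intervals within [0, dur).
complement_intervals <- function(iv, dur) {
  if (nrow(iv) == 0) return(cbind(start_s = 0, end_s = dur))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, ])
  }
  starts <- c(0, merged[, 2])
  ends <- c(merged[, 1], dur)
  keep <- ends > starts
  cbind(start_s = starts[keep], end_s = ends[keep])
}

#' Balance classes by down-sampling the interictal majority
#'
#' Interictal segments are down-sampled uniformly at random (seeded) to match
#' the ictal count, the standard remedy for the heavy class imbalance of
#' seizure data.
#'
#' @param ictal_x,interictal_x Segment arrays `(n, I, J)`.
#' @param seed Integer seed for the subsample.
#' @return List with `x` (ictal segments first) and `labels`.
#' @export
balance_classes <- function(ictal_x, interictal_x, seed = 1) {
  ni <- dim(ictal_x)[1]
  nm <- dim(interictal_x)[1]
  if (nm < ni)
    stop(sprintf(paste0("only %d interictal segments for %d ictal segments; ",
                        "extract more interictal data"), nm, ni))
  keep <- if (nm > ni) with_seed(seed, sort(sample.int(nm, ni))) else seq_len(nm)
  x <- array(0, c(2L * ni, dim(ictal_x)[2], dim(ictal_x)[3]))
  x[seq_len(ni), , ] <- ictal_x
  x[ni + seq_len(ni), , ] <- interictal_x[keep, , , drop = FALSE]
  list(x = x, labels = rep(c(1L, 0L), each = ni))
}

#' Per-channel statistics over a merged segment dataset
#'
#' Mean and standard deviation per channel, pooled over every segment and
#' sample. The population convention (divide by n) is used.
#'
#' @param x Segment array `(N, I, J)` or `(N, I, J, 1)`.
#' @return Object of class `channel_stats` with `mean` and `sd` per channel.
#' @export
channel_stats <- function(x) {
  d <- dim(x)
  J <- d[3]
  xm <- matrix(as.double(x), d[1] * d[2], J)
  mu <- colMeans(xm)
  s <- sqrt(colMeans(sweep(xm, 2, mu)^2))
  structure(list(mean = mu, sd = s), class = "channel_stats")
}

#' Z-score every channel using merged-dataset statistics
#'
#' Applies `(y - z_m) / s_d` per channel. Channels with zero spread are
#' guarded: their sd is replaced by 1, so a constant channel maps to all
#' zeros rather than faulting.
#'
#' @param x Segment array `(N, I, J)`.
#' @param stats A [channel_stats()]; computed from `x` if omitted.
#' @return Array of the same shape.
#' @export
zscore_channels <- function(x, stats = channel_stats(x)) {
  stopifnot(inherits(stats, "channel_stats"))
  d <- dim(x)
  sd_g <- ifelse(stats$sd > 0, stats$sd, 1)
  xm <- matrix(as.double(x), d[1] * d[2], d[3])
  xm <- sweep(sweep(xm, 2, stats$mean), 2, sd_g, "/")
  array(xm, d)
}

#' Scale a dataset globally to the unit interval
#'
#' One affine map for the whole dataset (not per channel): the global minimum
#' maps to 0 and the global maximum to 1, keeping original and reconstructed
#' segments on comparable scales. A constant dataset maps to all zeros.
#'
#' @param x Numeric array.
#' @param bounds Optional `(min, max)` to reuse (e.g. the training set's).
#' @return List with `values` and the `bounds` used.
#' @export
minmax_scale <- function(x, bounds = NULL) {
  if (is.null(bounds)) bounds <- range(x)
  span <- bounds[2] - bounds[1]
  values <- if (span <= 0) array(0, dim(x)) else (x - bounds[1]) / span
  list(values = values, bounds = bounds)
}

#' Invert the normalization of prepared values
#'
#' Maps values back from the unit interval to original signal units using the
#' recorded scale bounds and channel statistics, enabling inspection of
#' reconstructions in physical units.
#'
#' @param values Array `(N, I, J)` or `(N, I, J, 1)` of normalized values.
#' @param stats The [channel_stats()] used during preparation.
#' @param bounds The min-max `bounds` used during preparation.
#' @return Array of the same shape in original units.
#' @export
denormalize <- function(values, stats, bounds) {
  d <- dim(values)
  z <- values * (bounds[2] - bounds[1]) + bounds[1]
  J <- d[3]
  sd_g <- ifelse(stats$sd > 0, stats$sd, 1)
  zm <- matrix(as.double(z), d[1] * d[2], J)
  zm <- sweep(sweep(zm, 2, sd_g, "*"), 2, stats$mean, "+")
  array(zm, d)
}

#' Stratified fold assignment
#'
#' Assigns each segment to one of `k` folds so that fold sizes differ by at
#' most one and every fold matches the overall class proportions to within
#' one segment per class (seeded shuffle, then per-class round-robin).
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `0:(k-1)`.
#' @export
assign_folds <- function(labels, k = 10, seed = 1) {
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stop(sprintf("class %s has fewer than %d segments", cl, k))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L) %% k
    }
  })
  fold
}

#' Prepare a balanced, normalized, fold-assigned segment dataset
#'
#' Runs the fixed preparation order: balance the classes, z-score each
#' channel over the merged dataset, min-max scale globally to `[0, 1]`, add
#' the singleton depth axis, and assign stratified folds. Normalization
#' statistics are computed on the entire merged dataset before fold
#' splitting; this matches the preparation the models assume but leaks
#' scale information from test folds into training — see
#' [cross_validate()]'s `per_fold_normalization` for the leakage-free
#' variant (which requires `keep_raw = TRUE`).
#'
#' @param ictal_x,interictal_x Segment arrays `(n, I, J)`, e.g. from
#'   [extract_segments()] or [generate_segments()].
#' @param seed Seed controlling the balancing subsample and fold shuffle.
#' @param k Number of folds.
#' @param keep_raw Retain the unnormalized values (needed for per-fold
#'   normalization).
#' @return Object of class `eeg_dataset`: list with `x` (`(N, I, J, 1)`,
#'   values in `[0, 1]`), `labels`, `fold_ids`, `stats`, `bounds`.
#' @export
prepare_dataset <- function(ictal_x, interictal_x, seed = 1, k = 10,
                            keep_raw = FALSE) {
  bal <- balance_classes(ictal_x, interictal_x, seed = seed)
  stats <- channel_stats(bal$x)
  z <- zscore_channels(bal$x, stats)
  mm <- minmax_scale(z)
  d <- dim(mm$values)
  structure(list(
    x = array(mm$values, c(d, 1)), labels = bal$labels,
    fold_ids = assign_folds(bal$labels, k = k, seed = seed + 1L),
    stats = stats, bounds = mm$bounds, k = k,
    x_raw = if (keep_raw) bal$x else NULL
  ), class = "eeg_dataset")
}

#' Build a ready-to-train synthetic dataset
#'
#' Convenience wrapper chaining [generate_segments()] and
#' [prepare_dataset()].
#'
#' @param config A [synth_config()].
#' @param k Number of folds.
#' @param keep_raw See [prepare_dataset()].
#' @return An `eeg_dataset`.
#' @export
synthetic_dataset <- function(config, k = 10, keep_raw = FALSE) {
  seg <- generate_segments(config)
  n <- config$n_segments_per_class
  prepare_dataset(seg$x[seg$labels == 1, , , drop = FALSE],
                  seg$x[seg$labels == 0, , , drop = FALSE],
                  seed = config$seed, k = k, keep_raw = keep_raw)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "<eeg_dataset> %d segments (%d x %d x %d), %d ictal / %d interictal, %d folds\n",
    d[1], d[2], d[3], d[4], sum(x$labels == 1), sum(x$labels == 0), x$k))
  invisible(x)
}

#' Save / load a prepared dataset
#'
#' The container holds values, labels, fold ids, channel statistics and scale
#' bounds, so a saved dataset round-trips without re-running preparation.
#'
#' @param dataset An `eeg_dataset`.
#' @param path File path (RDS).
#' @return `path` (write) or the restored `eeg_dataset` (read).
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "eeg_dataset"))
  ds
}
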