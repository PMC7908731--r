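#' Mean-absolute-value feature series
#'
#' Frames of windowed mean-absolute-value (MAV) EMG features at the
#' decode rate. For `n` retained monopolar channels the feature vector
#' stacks the `n` single-ended channels followed by the `n(n-1)/2`
#' differential pairs, so 32 channels yield 528 features.
#'
#' @param values numeric matrix, features x frames (microvolts,
#'   nonnegative once a baseline has been subtracted and floored).
#' @param frame_rate frames per second (~30 for a 33-ms hop).
#' @param feature_names ordered feature labels.
#' @param buffer_ms trailing MAV window length in milliseconds.
#' @param frame_times optional vector of frame end-times (s).
#' @param warmup logical vector flagging frames whose buffer overlaps the
#'   filter warm-up transient at the start of the recording.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, frame_rate, feature_names = NULL,
                           buffer_ms = 300, frame_times = NULL,
                           warmup = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_config("values must be a numeric features x frames matrix")
  check_scalar_pos(frame_rate, "frame_rate")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(nrow(values)))
  if (length(feature_names) != nrow(values))
    abort_config("feature_names length must match feature rows")
  rownames(values) <- feature_names
  structure(
    list(values = values, frame_rate = frame_rate,
         feature_names = feature_names, buffer_ms = buffer_ms,
         frame_times = frame_times,
         warmup = warmup %||% rep(FALSE, ncol(values))),
    class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d feature(s) x %d frame(s) @ %.2f Hz (buffer %g ms)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$buffer_ms))
  invisible(x)
}

#' @export
dim.feature_series <- function(x) dim(x$values)

#' Expand monopolar channels with all differential pairs
#'
#' Appends every pairwise difference `channel_i - channel_j` (i < j, in
#' channel order) to the single-ended channels. For `n` channels the
#' result has `n + n(n-1)/2` channels; differencing cancels common-mode
#' interference between nearby electrodes and is where most of the 528
#' standard features come from.
#'
#' @param raw a [raw_emg()] with at least two channels.
#' @return A [raw_emg()] with single-ended channels first, then pairs
#'   labelled `"chA-chB"`.
#' @export
expand_differential <- function(raw) {
  if (!inherits(raw, "raw_emg")) abort_config("raw must be a raw_emg")
  n <- nrow(raw$samples)
  if (n < 2) abort_config("differential expansion needs >= 2 channels")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  diffs <- raw$samples[pairs[, "row"], , drop = FALSE] -
    raw$samples[pairs[, "col"], , drop = FALSE]
  ids <- c(raw$channel_ids,
           paste0(raw$channel_ids[pairs[, "row"]], "-",
                  raw$channel_ids[pairs[, "col"]]))
  raw_emg(rbind(raw$samples, diffs), raw$rate, ids)
}

#' Extract trailing-window MAV features
#'
#' Emits one frame per hop: the mean absolute value of the trailing
#' `buffer_ms` of each channel. Frames are causal (a frame ending at
#' sample `t` uses only samples `t - buffer + 1 .. t`) and the first
#' frame is emitted once a full buffer is available. The hop is
#' `round(rate / frame_rate)` whole samples — 33 samples at 1 kHz and
#' 30 Hz nominal, i.e. an effective 30.3 Hz with a 267-ms overlap.
#'
#' @param raw a (preprocessed, differential-expanded) [raw_emg()].
#' @param buffer_ms MAV window in milliseconds (default 300).
#' @param frame_rate nominal frames/s (default 30).
#' @return A [feature_series()]; frames whose window starts inside the
#'   first `buffer_ms` of the recording carry a warm-up flag.
#' @export
mav_features <- function(raw, buffer_ms = 300, frame_rate = 30) {
  if (!inherits(raw, "raw_emg")) abort_config("raw must be a raw_emg")
  check_scalar_pos(buffer_ms, "buffer_ms")
  check_scalar_pos(frame_rate, "frame_rate")
  buf <- round(buffer_ms * raw$rate / 1000)
  hop <- round(raw$rate / frame_rate)
  if (hop < 1) abort_config("frame_rate too high for sampling rate")
  n <- ncol(raw$samples)
  if (buf > n) abort_data("buffer longer than the recording")
  ends <- seq(buf, n, by = hop)
  # windowed sum via cumulative sums along time, per channel
  cs <- cbind(0, t(apply(abs(raw$samples), 1, cumsum)))
  vals <- (cs[, ends + 1L, drop = FALSE] - cs[, ends - buf + 1L, drop = FALSE]) / buf
  feature_series(vals,
                 frame_rate = raw$rate / hop,
                 feature_names = raw$channel_ids,
                 buffer_ms = buffer_ms,
                 frame_times = ends / raw$rate,
                 warmup = (ends - buf) < buf)
}

#' Baseline (resting) feature profile
#'
#' Average feature activity over a rest window — recorded while the user
#' supports the prosthesis in a neutral posture — used to zero out each
#' feature's resting level before training.
#'
#' @param features a [feature_series()] recorded at rest.
#' @param window_s length of the rest window to average, taken from the
#'   end of the series (default 10 s).
#' @return An object of class `baseline_profile`: per-feature means.
#' @export
estimate_baseline <- function(features, window_s = 10) {
  if (!inherits(features, "feature_series"))
    abort_config("features must be a feature_series")
  check_scalar_pos(window_s, "window_s")
  need <- ceiling(window_s * features$frame_rate)
  n <- ncol(features$values)
  if (n < need)
    abort_data(sprintf("need %.1f s of rest frames, have %.1f s",
                       window_s, n / features$frame_rate))
  idx <- seq(n - need + 1L, n)
  structure(
    list(mean_activity = rowMeans(features$values[, idx, drop = FALSE]),
         duration_s = window_s),
    class = "baseline_profile")
}

#' Subtract a baseline profile from a feature series
#'
#' Per-feature subtraction floored at zero: MAV features are magnitudes
#' and the decoders assume nonnegative inputs.
#'
#' @param features a [feature_series()].
#' @param baseline a `baseline_profile` from [estimate_baseline()].
#' @return The baseline-corrected [feature_series()].
#' @export
subtract_baseline <- function(features, baseline) {
  if (!inherits(baseline, "baseline_profile"))
    abort_config("baseline must be a baseline_profile")
  if (length(baseline$mean_activity) != nrow(features$values))
    abort_config("baseline length does not match feature count")
  if (!all(is.finite(baseline$mean_activity)))
    abort_data("non-finite baseline")
  out <- features
  out$values <- pmax(features$values - baseline$mean_activity, 0)
  out
}

#' Read / write feature series as wide CSV
#'
#' Wide format: `frame_time_s` plus one column per feature.
#'
#' @param path CSV file path.
#' @param frame_rate frames/s; inferred from `frame_time_s` when `NULL`.
#' @param buffer_ms window length metadata (default 300).
#' @return `read_feature_csv`: a [feature_series()].
#' @export
read_feature_csv <- function(path, frame_rate = NULL, buffer_ms = 300) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "frame_time_s")
    abort_data("first column must be frame_time_s")
  times <- df[[1]]
  if (is.null(frame_rate)) {
    if (length(times) < 2) abort_data("cannot infer frame rate")
    frame_rate <- 1 / stats::median(diff(times))
  }
  feature_series(t(as.matrix(df[, -1, drop = FALSE])), frame_rate,
                 feature_names = names(df)[-1], buffer_ms = buffer_ms,
                 frame_times = times)
}

#' @rdname read_feature_csv
#' @param features a [feature_series()].
#' @export
write_feature_csv <- function(features, path) {
  times <- features$frame_times %||%
    (seq_len(ncol(features$values)) / features$frame_rate)
  df <- data.frame(frame_time_s = times, t(features$values),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(features)
}
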