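#' Multichannel raw EMG recording
#'
#' Container for a monopolar (or differential-expanded) surface-EMG
#' recording: a channels-by-time matrix of amplitudes in microvolts plus
#' the sampling rate and channel bookkeeping. Recordings from the
#' 32-electrode sleeve this package targets are acquired at 1 kHz, but any
#' channel count and rate satisfying the filter constraints is accepted.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in samples/s (default 1000).
#' @param channel_ids character vector of channel labels, one per row.
#'   Defaults to `"ch1".."chN"`.
#' @param bad_channels character vector (subset of `channel_ids`) of
#'   channels to be dropped before any filtering or feature extraction,
#'   e.g. electrodes found shorted at setup.
#' @return An object of class `raw_emg`.
#' @export
raw_emg <- function(samples, rate = 1000, channel_ids = NULL,
                    bad_channels = character()) {
  if (!is.matrix(samples) || !is.numeric(samples))
    abort_config("samples must be a numeric channels x time matrix")
  check_scalar_pos(rate, "rate")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    abort_config("channel_ids length must equal the number of channel rows")
  if (anyDuplicated(channel_ids))
    abort_config("channel_ids must be unique")
  if (!all(bad_channels %in% channel_ids))
    abort_config("bad_channels must be a subset of channel_ids")
  rownames(samples) <- channel_ids
  structure(
    list(samples = samples, rate = rate, channel_ids = channel_ids,
         bad_channels = as.character(bad_channels)),
    class = "raw_emg")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raw_emg <- function(x) dim(x$samples)

drop_bad_channels <- function(raw) {
  if (!length(raw$bad_channels)) return(raw)
  keep <- setdiff(raw$channel_ids, raw$bad_channels)
  raw_emg(raw$samples[keep, , drop = FALSE], raw$rate, keep)
}

#' Read / write raw EMG as long-format CSV
#'
#' The on-disk format is tidy/long: columns `time_s`, `channel`,
#' `value_uV`. Channel order follows first appearance in the file.
#'
#' @param path CSV file path.
#' @param rate sampling rate; inferred from `time_s` spacing when `NULL`.
#' @return `read_raw_emg_csv`: a [raw_emg()]; `write_raw_emg_csv`: the
#'   input, invisibly.
#' @export
read_raw_emg_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "value_uV")
  if (!all(need %in% names(df)))
    abort_data("CSV must have columns time_s, channel, value_uV")
  chans <- unique(df$channel)
  times <- sort(unique(df$time_s))
  if (is.null(rate)) {
    if (length(times) < 2) abort_data("cannot infer rate from a single sample")
    rate <- 1 / stats::median(diff(times))
  }
  mat <- matrix(NA_real_, length(chans), length(times),
                dimnames = list(chans, NULL))
  mat[cbind(match(df$channel, chans), match(df$time_s, times))] <- df$value_uV
  if (anyNA(mat)) abort_data("missing samples: channels have unequal lengths")
  raw_emg(mat, rate = rate, channel_ids = chans)
}

#' @rdname read_raw_emg_csv
#' @param raw a [raw_emg()] object.
#' @export
write_raw_emg_csv <- function(raw, path) {
  n <- ncol(raw$samples)
  df <- data.frame(
    time_s = rep((seq_len(n) - 1) / raw$rate, each = nrow(raw$samples)),
    channel = rep(raw$channel_ids, times = n),
    value_uV = as.vector(raw$samples))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(raw)
}
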