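#' EMG preprocessing filter specification
#'
#' The standard acquisition chain for the surface-EMG sleeve: a 6th-order
#' high-pass Butterworth at 15 Hz (removes motion artifact and DC offset),
#' a 2nd-order low-pass Butterworth at 375 Hz (anti-aliasing / noise
#' ceiling) and narrow notches at the power-line fundamental and its first
#' two harmonics (60/120/180 Hz).
#'
#' @param highpass_order,highpass_hz high-pass Butterworth order and corner.
#' @param lowpass_order,lowpass_hz low-pass Butterworth order and corner.
#' @param notch_hz frequencies (Hz) to notch out; may be empty.
#' @param notch_q notch quality factor; Q = 30 gives a 2 Hz bandwidth at
#'   60 Hz, narrow enough to leave the EMG band intact.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_order = 6, highpass_hz = 15,
                        lowpass_order = 2, lowpass_hz = 375,
                        notch_hz = c(60, 120, 180), notch_q = 30) {
  if (highpass_order < 1 || lowpass_order < 1)
    abort_config("filter orders must be >= 1")
  check_scalar_pos(highpass_hz, "highpass_hz")
  check_scalar_pos(lowpass_hz, "lowpass_hz")
  check_scalar_pos(notch_q, "notch_q")
  if (highpass_hz >= lowpass_hz)
    abort_config("highpass_hz must be below lowpass_hz")
  structure(
    list(highpass_order = highpass_order, highpass_hz = highpass_hz,
         lowpass_order = lowpass_order, lowpass_hz = lowpass_hz,
         notch_hz = notch_hz, notch_q = notch_q),
    class = "filter_spec")
}

# RBJ biquad notch at f0 with quality q, for sampling rate `rate`.
notch_coefs <- function(f0, q, rate) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# The cascade as a list of {b, a} sections, in application order.
filter_sections <- function(spec, rate) {
  nyq <- rate / 2
  if (spec$lowpass_hz >= nyq)
    abort_config("sampling rate must exceed twice the low-pass corner")
  hp <- signal::butter(spec$highpass_order, spec$highpass_hz / nyq,
                       type = "high")
  lp <- signal::butter(spec$lowpass_order, spec$lowpass_hz / nyq,
                       type = "low")
  sections <- list(list(b = hp$b, a = hp$a), list(b = lp$b, a = lp$a))
  for (f0 in spec$notch_hz) {
    if (f0 >= nyq) abort_config("notch frequency above Nyquist")
    sections[[length(sections) + 1L]] <- notch_coefs(f0, spec$notch_q, rate)
  }
  sections
}

#' Frequency response of the preprocessing cascade
#'
#' Evaluates the designed cascade's transfer function at the requested
#' frequencies — the natural oracle for attenuation checks and for
#' plotting the chain's passband.
#'
#' @param spec a [filter_spec()].
#' @param freq_hz numeric vector of frequencies (Hz).
#' @param rate sampling rate (samples/s).
#' @return Numeric vector of gain magnitudes, one per frequency.
#' @export
filter_response <- function(spec, freq_hz, rate) {
  sections <- filter_sections(spec, rate)
  z <- exp(-1i * 2 * pi * freq_hz / rate)
  h <- rep(1 + 0i, length(z))
  for (s in sections) {
    num <- vapply(z, function(zz) sum(s$b * zz^(seq_along(s$b) - 1)),
                  complex(1))
    den <- vapply(z, function(zz) sum(s$a * zz^(seq_along(s$a) - 1)),
                  complex(1))
    h <- h * num / den
  }
  Mod(h)
}

#' Causally filter a raw EMG recording
#'
#' Applies the high-pass, low-pass and notch cascade forward-only
#' (sample `t` of the output depends only on inputs up to `t`), matching
#' the real-time contract of an online decoder. Channels flagged bad are
#' removed before filtering.
#'
#' @param raw a [raw_emg()] recording.
#' @param spec a [filter_spec()]; defaults to the standard chain.
#' @return A filtered [raw_emg()] with bad channels dropped.
#' @export
preprocess <- function(raw, spec = filter_spec()) {
  if (!inherits(raw, "raw_emg")) abort_config("raw must be a raw_emg")
  if (!all(is.finite(raw$samples))) abort_data("non-finite EMG samples")
  if (raw$rate < 2 * spec$lowpass_hz)
    abort_config("sampling rate below twice the low-pass corner")
  raw <- drop_bad_channels(raw)
  sections <- filter_sections(spec, raw$rate)
  out <- raw$samples
  for (s in sections) {
    out <- t(apply(out, 1, function(x) as.numeric(signal::filter(s$b, s$a, x))))
  }
  raw_emg(out, raw$rate, raw$channel_ids)
}
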