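#' Latching-filter configuration
#'
#' The latching filter is a recursive, nonlinear output smoother: per
#' DOF it moves the smoothed output a fraction `alpha` of the way from
#' the previous output toward the current decoder estimate, with
#' `alpha = clamp((|d| / d_full)^gamma, alpha_min, 1)` where `d` is the
#' estimate change. Small changes (jitter) are damped almost completely;
#' changes of at least `d_full` pass through unsmoothed (alpha = 1), so
#' large movements incur zero added latency.
#'
#' @param d_full estimate-change magnitude (fraction of the [-1, 1]
#'   range) at which smoothing vanishes; default 0.3.
#' @param gamma nonlinearity exponent >= 1 (default 2): larger values
#'   damp small jitter harder for the same `d_full`.
#' @param alpha_min smoothing floor in (0, 1] (default 0.01) so the
#'   output always tracks eventually.
#' @return An object of class `latch_config`.
#' @export
latch_config <- function(d_full = 0.3, gamma = 2, alpha_min = 0.01) {
  if (d_full <= 0 || d_full > 2) abort_config("d_full must be in (0, 2]")
  if (gamma < 1) abort_config("gamma must be >= 1")
  if (alpha_min <= 0 || alpha_min > 1)
    abort_config("alpha_min must be in (0, 1]")
  structure(list(d_full = d_full, gamma = gamma, alpha_min = alpha_min),
            class = "latch_config")
}

#' One latching-filter step
#'
#' @param state per-DOF previous smoothed output (numeric vector), e.g.
#'   rest `rep(0, d)` at stream start.
#' @param estimate current decoder estimate, in [-1, 1] per DOF.
#' @param config a [latch_config()].
#' @return `list(state = <new state>, output = <smoothed vector>)`; the
#'   new state equals the output.
#' @export
latch_step <- function(state, estimate, config = latch_config()) {
  if (!all(is.finite(estimate))) abort_data("non-finite decoder estimate")
  d <- estimate - state
  alpha <- clamp((abs(d) / config$d_full)^config$gamma,
                 config$alpha_min, 1)
  out <- state + alpha * d
  list(state = out, output = out)
}

#' Smooth a decoded kinematic trace with the latching filter
#'
#' Frame-wise application of [latch_step()] starting from rest.
#'
#' @param trace a [kinematic_trace()] of decoder output.
#' @param config a [latch_config()].
#' @return The smoothed [kinematic_trace()].
#' @export
latch_stream <- function(trace, config = latch_config()) {
  pos <- trace$positions
  state <- rep(0, nrow(pos))
  out <- pos
  for (t in seq_len(ncol(pos))) {
    st <- latch_step(state, pos[, t], config)
    state <- st$state
    out[, t] <- st$output
  }
  trace$positions <- out
  trace
}
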