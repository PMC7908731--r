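#' Synthetic-EMG simulator configuration
#'
#' Forward model emulating a mimicry-training recording: each DOF
#' excursion is rectified into two nonnegative directional drives
#' (flexion and extension use different muscles), mixed through a
#' nonnegative synergy matrix into muscle activations, and projected
#' through a nonnegative muscle-to-channel mixing matrix into
#' per-channel envelopes. Surface EMG is then white Gaussian noise
#' amplitude-modulated by envelope + baseline at the acquisition rate,
#' so the mean-absolute-value features downstream recover the envelope.
#'
#' @param n_dof number of degrees-of-freedom (2 or 5 in the standard
#'   protocols).
#' @param dof_names DOF labels (defaults to the phase-1 or phase-2 sets
#'   when `n_dof` is 2 or 5).
#' @param n_channels monopolar electrode count (default 32).
#' @param n_muscles number of simulated muscles (default `2 * n_dof`,
#'   one per drive direction).
#' @param synergy nonnegative `n_muscles x 2 n_dof` drive-to-muscle
#'   matrix; default: each direction owns one muscle plus mild seeded
#'   cross-talk.
#' @param channel_mix nonnegative `n_channels x n_muscles` matrix;
#'   default: seeded smooth spatial tuning of channels over muscles.
#' @param baseline_uV resting noise amplitude per channel (default 3).
#' @param snr_db feature-domain signal-to-noise ratio: 10 log10 of mean
#'   squared envelope-driven feature excursion over the variance of the
#'   baseline-only feature noise (default 20).
#' @param rate acquisition sampling rate (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_dof = 2, dof_names = NULL, n_channels = 32,
                         n_muscles = 2 * n_dof, synergy = NULL,
                         channel_mix = NULL, baseline_uV = 3,
                         snr_db = 20, rate = 1000, seed = 1) {
  if (is.null(dof_names))
    dof_names <- if (n_dof == 2) c("hand", "wrist")
      else if (n_dof == 5) phase2_dofs()
      else paste0("dof", seq_len(n_dof))
  if (length(dof_names) != n_dof) abort_config("dof_names length != n_dof")
  if (is.null(synergy)) {
    synergy <- with_seed(seed * 7L + 1L, {
      m <- matrix(0, n_muscles, 2 * n_dof)
      m[cbind(seq_len(n_muscles), rep_len(seq_len(2 * n_dof), n_muscles))] <- 1
      m + matrix(stats::runif(length(m), 0, 0.15), nrow(m))
    })
  }
  if (is.null(channel_mix)) {
    channel_mix <- with_seed(seed * 7L + 2L, {
      # distinct muscle bellies under distinct electrodes: evenly spaced
      # centres (with seeded jitter) so antagonists are spatially separable
      spacing <- n_channels / n_muscles
      centre <- (seq_len(n_muscles) - 0.5) * spacing +
        stats::runif(n_muscles, -0.25, 0.25) * spacing
      width <- spacing / 2
      w <- outer(seq_len(n_channels), centre,
                 function(ch, mu) exp(-(ch - mu)^2 / (2 * width^2)))
      w + matrix(stats::runif(length(w), 0, 0.02), nrow(w))
    })
  }
  if (any(synergy < 0) || any(channel_mix < 0))
    abort_config("mixing matrices must be nonnegative")
  if (nrow(synergy) != n_muscles || ncol(synergy) != 2 * n_dof)
    abort_config("synergy must be n_muscles x 2*n_dof")
  if (nrow(channel_mix) != n_channels || ncol(channel_mix) != n_muscles)
    abort_config("channel_mix must be n_channels x n_muscles")
  if (!is.finite(snr_db)) abort_config("snr_db must be finite")
  structure(
    list(n_dof = n_dof, dof_names = dof_names, n_channels = n_channels,
         n_muscles = n_muscles, synergy = synergy,
         channel_mix = channel_mix, baseline_uV = baseline_uV,
         snr_db = snr_db, rate = rate, seed = as.integer(seed)),
    class = "synth_config")
}

# envelope gain hitting the configured feature-domain SNR. Calibrated
# once per config against full-scale single-DOF excursions (not the
# realized kinematics), so envelopes stay linear in the drive.
synth_gain <- function(config) {
  buf <- round(0.3 * config$rate)
  c2 <- 2 / pi
  v_base <- config$baseline_uV^2 * (1 - c2) / buf
  ref <- config$channel_mix %*% config$synergy  # channels x 2 n_dof
  ref <- ref[ref > 1e-12]
  if (!length(ref)) return(1)
  sqrt(10^(config$snr_db / 10) * v_base / (c2 * mean(ref^2)))
}

# per-channel envelopes (channels x frames) from kinematics, unit gain
synth_envelope <- function(kinematics, config) {
  pos <- kinematics$positions
  if (nrow(pos) != config$n_dof) abort_config("DOF count mismatch")
  drive <- rbind(pmax(pos, 0), pmax(-pos, 0))   # 2d x frames
  act <- pmax(config$synergy %*% drive, 0)
  config$channel_mix %*% act
}

#' Simulate raw EMG from a kinematic trace
#'
#' Runs the synergy forward model and modulates seeded white Gaussian
#' noise by the resulting envelopes. The envelope gain is calibrated so
#' the feature-domain SNR matches `config$snr_db` (see
#' [synth_config()]); the calibration assumes the default 300-ms MAV
#' window.
#'
#' @param kinematics a [kinematic_trace()] (e.g. from
#'   [gen_schedule_kinematics()]).
#' @param config a [synth_config()].
#' @return A [raw_emg()] at `config$rate` with
#'   `frames * round(rate / frame_rate)` samples.
#' @export
gen_emg <- function(kinematics, config) {
  if (max(abs(kinematics$positions)) > 1 + 1e-9)
    abort_config("kinematics must lie in [-1, 1]")
  env <- synth_envelope(kinematics, config)
  hop <- round(config$rate / kinematics$frame_rate)
  n <- ncol(env) * hop
  gain <- synth_gain(config)
  # sample-rate envelope by linear interpolation between frame ends
  frame_samp <- seq_len(ncol(env)) * hop
  env_s <- t(apply(env, 1, function(e)
    stats::approx(frame_samp, e, xout = seq_len(n), rule = 2)$y))
  amp <- config$baseline_uV + gain * env_s
  noise <- with_seed(config$seed,
                     matrix(stats::rnorm(length(amp)), nrow(amp)))
  raw_emg(amp * noise, rate = config$rate,
          channel_ids = paste0("ch", seq_len(config$n_channels)))
}

#' Simulate a complete mimicry-training dataset
#'
#' End-to-end forward simulation of a training session: renders the
#' schedule's kinematics, synthesizes raw EMG, runs the standard feature
#' pipeline (causal filtering, differential expansion, MAV extraction,
#' baseline subtraction using a leading rest period), and pairs each
#' feature frame with the ground-truth kinematics at the centre of its
#' MAV window, so the paired data carry no intrinsic lag. An artificial
#' feature/kinematic lag can be injected (positive = kinematics delayed)
#' to exercise [align_lag()].
#'
#' @param schedule a `schedule` from [build_phase1_schedule()] /
#'   [build_phase2_schedule()], or any schedule-shaped object.
#' @param config a [synth_config()] with `n_dof` matching the schedule.
#' @param lag_frames integer lag to inject (default 0).
#' @param periods optional period subset passed to
#'   [gen_schedule_kinematics()].
#' @param rest_gap_s inter-trial rest (default 2 s).
#' @param rest_lead_s leading rest used for the baseline profile
#'   (default 12 s, covering the 10-s baseline window).
#' @param filter optional [filter_spec()]; `NULL` skips filtering (the
#'   simulator's carrier is already broadband).
#' @return A `synth_dataset`: `$train` (a [training_set()] of
#'   baseline-subtracted features paired with kinematics), `$raw`,
#'   `$kinematics` (the full rendered trace), `$baseline`, `$config`,
#'   `$lag_frames`.
#' @export
make_training_set <- function(schedule, config, lag_frames = 0,
                              periods = NULL, rest_gap_s = 2,
                              rest_lead_s = 12, filter = filter_spec()) {
  hop <- round(config$rate / 30)
  fr <- config$rate / hop
  kin <- gen_schedule_kinematics(schedule, periods = periods,
                                 frame_rate = fr,
                                 rest_gap_s = rest_gap_s)
  lead <- matrix(0, nrow(kin$positions), round(rest_lead_s * fr))
  nlead <- ncol(lead)
  kin_full <- kinematic_trace(
    cbind(lead, kin$positions), fr, kin$dof_names,
    trial_boundaries = kin$trial_boundaries + nlead,
    trial_info = transform(kin$trial_info,
                           start_frame = start_frame + nlead,
                           end_frame = end_frame + nlead))
  raw <- gen_emg(kin_full, config)
  pre <- if (is.null(filter)) drop_bad_channels(raw)
    else preprocess(raw, filter)
  feats <- mav_features(expand_differential(pre), buffer_ms = 300,
                        frame_rate = 30)
  buf <- round(0.3 * config$rate)
  # baseline from the leading rest (frames fully inside it)
  rest_frames <- which(feats$frame_times <= rest_lead_s)
  if (length(rest_frames) < ceiling(10 * fr))
    abort_config("rest_lead_s too short for the 10-s baseline window")
  rest_feats <- feats
  rest_feats$values <- feats$values[, rest_frames, drop = FALSE]
  baseline <- estimate_baseline(rest_feats, window_s = 10)
  feats <- subtract_baseline(feats, baseline)
  # pair feature frame k (window end sample buf + hop (k - 1)) with the
  # last kinematic frame at or before the MAV window centre
  s <- floor((buf - (buf - 1) / 2 - hop) / hop)
  n_feat <- ncol(feats$values)
  n_kin <- ncol(kin_full$positions)
  kin_trial <- integer(n_kin)
  for (i in seq_len(nrow(kin_full$trial_info)))
    kin_trial[kin_full$trial_info$start_frame[i]:
                kin_full$trial_info$end_frame[i]] <- i
  L <- as.integer(lag_frames)
  fi <- which(seq_len(n_feat) + s - L >= 1 &
                seq_len(n_feat) + s - L <= n_kin)
  ki <- fi + s - L
  feats$values <- feats$values[, fi, drop = FALSE]
  feats$warmup <- feats$warmup[fi]
  feats$frame_times <- feats$frame_times[fi]
  kin_paired <- kinematic_trace(
    kin_full$positions[, ki, drop = FALSE], fr, kin_full$dof_names)
  train <- training_set(feats, kin_paired, kin_trial[ki],
                        trial_info = kin_full$trial_info)
  structure(
    list(train = train, raw = raw, kinematics = kin_full,
         baseline = baseline, config = config, lag_frames = L),
    class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d DOF, %d channel(s), %.0f dB SNR, seed %d\n",
              x$config$n_dof, x$config$n_channels, x$config$snr_db,
              x$config$seed))
  print(x$train)
  invisible(x)
}
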