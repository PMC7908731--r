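# Shared fixtures, built in code. Expensive simulated datasets and fits
# are cached for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# reduced two-DOF mimicry schedule: `reps` trials of each of the four
# individual phase-one movements
mini_schedule <- function(reps = 3) {
  mv <- emgdec:::phase1_movements()
  trials <- list()
  for (m in mv) for (r in seq_len(reps))
    trials[[length(trials) + 1L]] <- list(move = m, rep = r,
                                          period = "mini")
  emgdec:::new_schedule(trials, c("hand", "wrist"), phase = 1)
}

mini_config <- function(seed = 3, snr_db = 20, n_channels = 8) {
  synth_config(n_dof = 2, n_channels = n_channels, snr_db = snr_db,
               seed = seed)
}

# simulated training session (cached per parameter combination)
mini_dataset <- function(seed = 3, snr_db = 20, reps = 3,
                         n_channels = 8, lag_frames = 0) {
  key <- paste("ds", seed, snr_db, reps, n_channels, lag_frames,
               sep = "_")
  cached(key, make_training_set(mini_schedule(reps),
                                mini_config(seed, snr_db, n_channels),
                                lag_frames = lag_frames))
}

# held-out session from an independent noise seed
mini_testset <- function(snr_db = 20, reps = 2, n_channels = 8) {
  mini_dataset(seed = 99, snr_db = snr_db, reps = reps,
               n_channels = n_channels)
}

mini_fit <- function(decoder, seed = 3, snr_db = 20, reps = 3,
                     n_channels = 8, k = 20) {
  key <- paste("fit", decoder, seed, snr_db, reps, n_channels, k,
               sep = "_")
  cached(key, train_decoder(mini_dataset(seed, snr_db, reps,
                                         n_channels)$train,
                            decoder, seed = seed, k = k))
}

# smooth random kinematics in [-1, 1] for regression-style fixtures
smooth_kinematics <- function(n_frames, n_dof = 2, seed = 1,
                              frame_rate = 30) {
  set.seed(seed)
  pos <- t(sapply(seq_len(n_dof), function(i) {
    x <- stats::filter(rnorm(n_frames), rep(1 / 15, 15), circular = TRUE)
    x <- as.numeric(x)
    0.9 * x / max(abs(x))
  }))
  kinematic_trace(pos, frame_rate,
                  dof_names = paste0("dof", seq_len(n_dof)))
}
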