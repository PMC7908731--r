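#' Paired features + kinematics for decoder training
#'
#' Frame-aligned feature and kinematic series with trial boundaries and
#' provenance (which protocol period produced each trial). All decoders
#' train from this container.
#'
#' @param features a [feature_series()].
#' @param kinematics a [kinematic_trace()] with the same frame count and
#'   frame rate.
#' @param trial_frames integer vector, one entry per frame: the trial
#'   number the frame belongs to, 0 for inter-trial rest. Defaults to all
#'   frames in one trial.
#' @param trial_info optional data.frame of per-trial provenance.
#' @return An object of class `training_set`.
#' @export
training_set <- function(features, kinematics, trial_frames = NULL,
                         trial_info = NULL) {
  if (!inherits(features, "feature_series"))
    abort_config("features must be a feature_series")
  if (!inherits(kinematics, "kinematic_trace"))
    abort_config("kinematics must be a kinematic_trace")
  nf <- ncol(features$values); nk <- ncol(kinematics$positions)
  if (nf != nk)
    abort_config("features and kinematics must have equal frame counts (",
                 nf, " vs ", nk, ")")
  if (abs(features$frame_rate - kinematics$frame_rate) >
      1e-6 * features$frame_rate)
    abort_config("features and kinematics must share a frame rate")
  trial_frames <- trial_frames %||% rep(1L, nf)
  if (length(trial_frames) != nf)
    abort_config("trial_frames must have one entry per frame")
  structure(
    list(features = features, kinematics = kinematics,
         trial_frames = as.integer(trial_frames), trial_info = trial_info),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d feature(s), %d DOF, %d frame(s) (%.1f s), %d trial(s)\n",
              nrow(x$features$values), nrow(x$kinematics$positions),
              ncol(x$features$values),
              ncol(x$features$values) / x$features$frame_rate,
              length(setdiff(unique(x$trial_frames), 0L))))
  invisible(x)
}

n_trials <- function(set) length(setdiff(unique(set$trial_frames), 0L))

set_duration_s <- function(set) ncol(set$features$values) / set$features$frame_rate

# frame index ranges per trial (list keyed by trial id, in order)
trial_frame_ranges <- function(set) {
  ids <- setdiff(unique(set$trial_frames), 0L)
  lapply(ids, function(id) which(set$trial_frames == id))
}

subset_training_set <- function(set, frames) {
  feats <- set$features
  feats$values <- feats$values[, frames, drop = FALSE]
  feats$warmup <- feats$warmup[frames]
  feats$frame_times <- feats$frame_times[frames]
  kin <- set$kinematics
  kin$positions <- kin$positions[, frames, drop = FALSE]
  kin$trial_boundaries <- integer()
  tf <- set$trial_frames[frames]
  training_set(feats, kin, tf, set$trial_info)
}

#' Merge two training sets into one of balanced duration
#'
#' Concatenates two sets (e.g. two protocol periods) along the frame
#' axis. So that a decoder comparison is not confounded by training-data
#' quantity, a merge intended to balance two conditions can first be
#' equalized: if the durations differ, the longer set is truncated at
#' the trial boundary closest to the shorter set's duration (with a
#' warning). Provenance (trial periods) is preserved; trial numbers of
#' `b` are offset past those of `a`.
#'
#' @param a,b `training_set`s with identical feature spaces and frame
#'   rates.
#' @param equalize truncate the longer input to match the shorter before
#'   concatenating (default TRUE).
#' @return A merged [training_set()].
#' @export
merge_training_sets <- function(a, b, equalize = TRUE) {
  if (!inherits(a, "training_set") || !inherits(b, "training_set"))
    abort_config("inputs must be training_sets")
  if (nrow(a$features$values) != nrow(b$features$values))
    abort_config("feature dimensionalities differ")
  if (nrow(a$kinematics$positions) != nrow(b$kinematics$positions))
    abort_config("DOF counts differ")
  if (abs(a$features$frame_rate - b$features$frame_rate) >
      1e-6 * a$features$frame_rate)
    abort_config("frame rates differ")
  if (equalize && abs(set_duration_s(a) - set_duration_s(b)) >
      0.5 / a$features$frame_rate) {
    if (set_duration_s(a) > set_duration_s(b)) a <- truncate_to(a, b)
    else b <- truncate_to(b, a)
  }
  feats <- a$features
  feats$values <- cbind(a$features$values, b$features$values)
  feats$warmup <- c(a$features$warmup, b$features$warmup)
  feats$frame_times <- NULL
  kin <- a$kinematics
  na <- ncol(a$kinematics$positions)
  kin$positions <- cbind(a$kinematics$positions, b$kinematics$positions)
  kin$trial_boundaries <- c(a$kinematics$trial_boundaries,
                            b$kinematics$trial_boundaries + na)
  kin$trial_info <- NULL
  offset <- max(0L, a$trial_frames)
  tfb <- ifelse(b$trial_frames == 0L, 0L, b$trial_frames + offset)
  training_set(feats, kin, c(a$trial_frames, tfb),
               trial_info = rbind_safe(a$trial_info, b$trial_info))
}

rbind_safe <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  common <- intersect(names(a), names(b))
  rbind(a[common], b[common])
}

# truncate `long` at the trial boundary nearest the duration of `short`
truncate_to <- function(long, short) {
  target <- ncol(short$features$values)
  ranges <- trial_frame_ranges(long)
  ends <- vapply(ranges, max, integer(1))
  cut <- ends[which.min(abs(ends - target))]
  warning(sprintf(
    "training sets differ in duration (%.1f s vs %.1f s); truncating at a trial boundary to %.1f s",
    set_duration_s(long), set_duration_s(short), cut / long$features$frame_rate))
  subset_training_set(long, seq_len(cut))
}
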