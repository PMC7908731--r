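#' Movement and combination-movement trial specifications
#'
#' A `movement_spec` is one trapezoidal mimicry-training movement: the
#' prosthesis ramps one or more degrees-of-freedom (DOFs) from rest to a
#' target position, holds, and ramps back. Sign convention: +1 =
#' flexion/close/pronation, -1 = extension/open/supination, 0 = rest.
#' Multi-DOF grips (e.g. a grasp flexing thumb, index and the coupled
#' middle-ring-little digits together) list several DOFs moving as one.
#'
#' @param dof character vector of DOF names moved together.
#' @param direction +1 or -1 per DOF (recycled if scalar).
#' @param amplitude fraction of the movement window reached (default 1).
#' @param rise_s,hold_s,fall_s ramp-up, plateau and ramp-down durations
#'   in seconds. The standard individual trial is 0.7/3.0/0.7 (4.4 s
#'   total); the longer variant is 0.7/5.2/0.7 (6.6 s total).
#' @param label human-readable movement name.
#' @return An object of class `movement_spec`.
#' @export
movement_spec <- function(dof, direction = 1, amplitude = 1,
                          rise_s = 0.7, hold_s = 3, fall_s = 0.7,
                          label = NULL) {
  direction <- rep_len(direction, length(dof))
  if (!all(direction %in% c(-1, 1)))
    abort_config("direction must be +1 or -1")
  if (abs(amplitude) > 1) abort_config("|amplitude| must be <= 1")
  if (min(rise_s, hold_s, fall_s) < 0)
    abort_config("durations must be nonnegative")
  structure(
    list(dof = dof, direction = direction, amplitude = amplitude,
         rise_s = rise_s, hold_s = hold_s, fall_s = fall_s,
         label = label %||% paste0(dof, ifelse(direction > 0, "+", "-"),
                                   collapse = "&")),
    class = "movement_spec")
}

#' @rdname movement_spec
#' @param primary,secondary `movement_spec`s for the leading and trailing
#'   movement of a combination trial. The secondary starts
#'   `secondary_delay_s` after the primary reaches its plateau and must
#'   finish before the primary starts its return ramp, so both DOF groups
#'   are simultaneously at full excursion during the middle of the trial.
#' @param secondary_delay_s onset delay after the primary plateau (0.4 s).
#' @export
combination_spec <- function(primary, secondary, secondary_delay_s = 0.4) {
  if (!inherits(primary, "movement_spec") ||
      !inherits(secondary, "movement_spec"))
    abort_config("primary and secondary must be movement_specs")
  if (length(intersect(primary$dof, secondary$dof)))
    abort_config("primary and secondary must use disjoint DOFs")
  onset <- primary$rise_s + secondary_delay_s
  sec_end <- onset + secondary$rise_s + secondary$hold_s + secondary$fall_s
  if (sec_end > primary$rise_s + primary$hold_s + 1e-9)
    abort_config("secondary movement would outlast the primary plateau")
  structure(
    list(primary = primary, secondary = secondary,
         secondary_delay_s = secondary_delay_s,
         label = paste(primary$label, "then", secondary$label)),
    class = "combination_spec")
}

trial_duration <- function(move) {
  if (inherits(move, "combination_spec")) move <- move$primary
  move$rise_s + move$hold_s + move$fall_s
}

# trapezoid value at times t (vectorized)
trapezoid_at <- function(t, rise, hold, fall, amp) {
  total <- rise + hold + fall
  v <- numeric(length(t))
  inr <- t >= 0 & t < rise
  v[inr] <- if (rise > 0) amp * t[inr] / rise else amp
  v[t >= rise & t < rise + hold] <- amp
  inf <- t >= rise + hold & t < total
  v[inf] <- if (fall > 0) amp * (total - t[inf]) / fall else 0
  v
}

#' Kinematic trace
#'
#' Per-DOF normalized prosthesis positions in [-1, 1] on a regular frame
#' grid, optionally carrying trial boundaries and provenance.
#'
#' @param positions numeric matrix, DOF x frames, values in [-1, 1].
#' @param frame_rate frames per second.
#' @param dof_names DOF labels (rownames).
#' @param trial_boundaries integer frame indices where trials start.
#' @param trial_info optional data.frame (one row per trial: label,
#'   period, start/end frames).
#' @return An object of class `kinematic_trace`.
#' @export
kinematic_trace <- function(positions, frame_rate, dof_names = NULL,
                            trial_boundaries = integer(),
                            trial_info = NULL) {
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = 1)
  if (max(abs(positions)) > 1 + 1e-9)
    abort_config("positions must lie in [-1, 1]")
  check_scalar_pos(frame_rate, "frame_rate")
  if (is.null(dof_names)) dof_names <- rownames(positions) %||%
      paste0("dof", seq_len(nrow(positions)))
  rownames(positions) <- dof_names
  structure(
    list(positions = positions, frame_rate = frame_rate,
         dof_names = dof_names, trial_boundaries = trial_boundaries,
         trial_info = trial_info),
    class = "kinematic_trace")
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cat(sprintf("<kinematic_trace> %d DOF x %d frame(s) @ %.2f Hz (%.1f s, %d trial(s))\n",
              nrow(x$positions), ncol(x$positions), x$frame_rate,
              ncol(x$positions) / x$frame_rate, length(x$trial_boundaries)))
  invisible(x)
}

#' @export
dim.kinematic_trace <- function(x) dim(x$positions)

#' Generate the kinematics of a single mimicry trial
#'
#' Samples the piecewise-linear trapezoid (or nested combination
#' trapezoids) on a regular frame grid starting at t = 0. The trace ends
#' within one frame of rest; schedule-level generation inserts explicit
#' rest gaps so concatenated traces start and end exactly at rest.
#'
#' @param spec a [movement_spec()].
#' @param frame_rate frames per second.
#' @param dof_names full DOF set for the output rows (defaults to the
#'   DOFs the spec moves).
#' @return A [kinematic_trace()] covering rise + hold + fall seconds.
#' @export
gen_individual_trial <- function(spec, frame_rate = 30, dof_names = NULL) {
  if (!inherits(spec, "movement_spec")) abort_config("spec must be a movement_spec")
  check_scalar_pos(frame_rate, "frame_rate")
  dof_names <- dof_names %||% spec$dof
  total <- trial_duration(spec)
  t <- seq(0, total, by = 1 / frame_rate)
  pos <- matrix(0, length(dof_names), length(t),
                dimnames = list(dof_names, NULL))
  prof <- trapezoid_at(t, spec$rise_s, spec$hold_s, spec$fall_s,
                       spec$amplitude)
  for (i in seq_along(spec$dof))
    pos[spec$dof[i], ] <- spec$direction[i] * prof
  kinematic_trace(pos, frame_rate, dof_names,
                  trial_boundaries = 1L,
                  trial_info = data.frame(label = spec$label,
                                          start_frame = 1L,
                                          end_frame = length(t)))
}

#' @rdname gen_individual_trial
#' @export
gen_combination_trial <- function(spec, frame_rate = 30, dof_names = NULL) {
  if (!inherits(spec, "combination_spec"))
    abort_config("spec must be a combination_spec")
  check_scalar_pos(frame_rate, "frame_rate")
  pri <- spec$primary; sec <- spec$secondary
  dof_names <- dof_names %||% c(pri$dof, sec$dof)
  total <- trial_duration(pri)
  t <- seq(0, total, by = 1 / frame_rate)
  pos <- matrix(0, length(dof_names), length(t),
                dimnames = list(dof_names, NULL))
  prof_p <- trapezoid_at(t, pri$rise_s, pri$hold_s, pri$fall_s, pri$amplitude)
  onset <- pri$rise_s + spec$secondary_delay_s
  prof_s <- trapezoid_at(t - onset, sec$rise_s, sec$hold_s, sec$fall_s,
                         sec$amplitude)
  for (i in seq_along(pri$dof)) pos[pri$dof[i], ] <- pri$direction[i] * prof_p
  for (i in seq_along(sec$dof)) pos[sec$dof[i], ] <- sec$direction[i] * prof_s
  kinematic_trace(pos, frame_rate, dof_names,
                  trial_boundaries = 1L,
                  trial_info = data.frame(label = spec$label,
                                          start_frame = 1L,
                                          end_frame = length(t)))
}

phase1_movements <- function() {
  list(close    = movement_spec("hand",  1, label = "close hand"),
       open     = movement_spec("hand", -1, label = "open hand"),
       pronate  = movement_spec("wrist",  1, label = "pronate"),
       supinate = movement_spec("wrist", -1, label = "supinate"))
}

# primary gets the long 0.7/5.2/0.7 profile in a combination trial
as_primary <- function(m) {
  movement_spec(m$dof, m$direction, m$amplitude, 0.7, 5.2, 0.7, m$label)
}

#' Build the two-DOF training schedule (phase one)
#'
#' Three training periods over the hand open/close and wrist rotation
#' DOFs: period 1 = 12 trials each of the four individual movements
#' (close, open, pronate, supinate; 48 trials of 4.4 s); period 2 = 4
#' trials each of the same movements (16 trials); period 3 = 4 trials
#' each of the eight ordered combination movements (32 trials of 6.6 s).
#' Trials are blocked by movement in the listed order; pass
#' `shuffle_seed` to permute trial order within each period.
#'
#' @param shuffle_seed optional integer; when given, trial order within
#'   each period is permuted reproducibly.
#' @return An object of class `schedule`.
#' @export
build_phase1_schedule <- function(shuffle_seed = NULL) {
  mv <- phase1_movements()
  combos <- list(c("close", "pronate"), c("close", "supinate"),
                 c("open", "pronate"), c("open", "supinate"),
                 c("pronate", "close"), c("supinate", "close"),
                 c("pronate", "open"), c("supinate", "open"))
  trials <- list()
  add <- function(move, rep_i, period) {
    trials[[length(trials) + 1L]] <<- list(move = move, rep = rep_i,
                                           period = period)
  }
  for (m in mv) for (r in 1:12) add(m, r, "period1")
  for (m in mv) for (r in 1:4) add(m, r, "period2")
  for (cm in combos) {
    spec <- combination_spec(as_primary(mv[[cm[1]]]), mv[[cm[2]]])
    for (r in 1:4) add(spec, r, "period3")
  }
  new_schedule(trials, dof_names = c("hand", "wrist"), phase = 1,
               shuffle_seed = shuffle_seed)
}

phase2_dofs <- function() c("thumb", "index", "mrl", "wristFlex", "wristRot")

phase2_wrist_movements <- function() {
  list(movement_spec("wristFlex",  1, label = "wrist flexion"),
       movement_spec("wristFlex", -1, label = "wrist extension"),
       movement_spec("wristRot",   1, label = "pronation"),
       movement_spec("wristRot",  -1, label = "supination"))
}

#' Build the five-DOF training schedule (phase two)
#'
#' Four training periods over thumb, index, coupled middle-ring-little,
#' wrist flexion and wrist rotation. Period 1 = 4 trials per DOF of
#' individual 0.7/5.2/0.7 movements (20 trials). Periods 2-4 each pair a
#' grip movement (grasp, open and pinch respectively) with the four
#' wrist movements: the grip alone, four grip-then-wrist combinations
#' and four wrist-then-grip combinations — 9 sequences x 4 trials = 36
#' trials per period.
#'
#' @inheritParams build_phase1_schedule
#' @return An object of class `schedule`.
#' @export
build_phase2_schedule <- function(shuffle_seed = NULL) {
  dofs <- phase2_dofs()
  long <- function(dof, dir, lab) movement_spec(dof, dir, 1, 0.7, 5.2, 0.7, lab)
  trials <- list()
  add <- function(move, rep_i, period) {
    trials[[length(trials) + 1L]] <<- list(move = move, rep = rep_i,
                                           period = period)
  }
  for (d in dofs) for (r in 1:4) add(long(d, 1, paste0(d, " flexion")), r,
                                     "period1")
  grips <- list(
    grasp = c("thumb", "index", "mrl"),
    open  = c("thumb", "index", "mrl"),
    pinch = c("thumb", "index"))
  grip_dir <- c(grasp = 1, open = -1, pinch = 1)
  wrists <- phase2_wrist_movements()
  for (g in names(grips)) {
    period <- paste0("period", 1 + match(g, names(grips)))
    grip_long <- long(grips[[g]], grip_dir[[g]], g)
    grip_short <- movement_spec(grips[[g]], grip_dir[[g]], 1, 0.7, 3, 0.7, g)
    seqs <- c(list(grip_long),
              lapply(wrists, function(w) combination_spec(grip_long, w)),
              lapply(wrists, function(w)
                combination_spec(as_primary(w), grip_short)))
    for (s in seqs) for (r in 1:4) add(s, r, period)
  }
  new_schedule(trials, dof_names = dofs, phase = 2,
               shuffle_seed = shuffle_seed)
}

new_schedule <- function(trials, dof_names, phase, shuffle_seed = NULL) {
  if (!is.null(shuffle_seed)) {
    periods <- vapply(trials, function(tr) tr$period, character(1))
    ord <- unlist(lapply(split(seq_along(trials), periods), function(idx) {
      idx[sample_seeded(length(idx), shuffle_seed + match(periods[idx[1]],
                                                          unique(periods)))]
    }), use.names = FALSE)
    # keep periods in their protocol order
    ord <- ord[order(match(periods[ord], unique(periods)))]
    trials <- trials[ord]
  }
  structure(list(trials = trials, dof_names = dof_names, phase = phase),
            class = "schedule")
}

# seeded permutation without touching the global RNG state
sample_seeded <- function(n, seed) {
  rng <- local_rng(seed)
  order(rng$runif(n))
}

# small counter-free RNG wrapper: save/restore .Random.seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  use <- function(f, ...) {
    assign(".Random.seed", state, envir = globalenv())
    out <- f(...)
    state <<- get(".Random.seed", globalenv())
    restore()
    out
  }
  list(runif = function(n) use(stats::runif, n),
       rnorm = function(n, ...) use(stats::rnorm, n, ...))
}

#' @export
print.schedule <- function(x, ...) {
  periods <- vapply(x$trials, function(tr) tr$period, character(1))
  cat(sprintf("<schedule> phase %s: %d trial(s), DOFs: %s\n", x$phase,
              length(x$trials), paste(x$dof_names, collapse = ", ")))
  print(table(periods))
  invisible(x)
}

#' Number of trials per schedule period
#' @param schedule a [build_phase1_schedule()] / [build_phase2_schedule()] result.
#' @return Named integer vector of trial counts.
#' @export
schedule_trial_counts <- function(schedule) {
  periods <- vapply(schedule$trials, function(tr) tr$period, character(1))
  table(factor(periods, levels = unique(periods)))
}

#' Render a schedule (or subset of its periods) as one kinematic trace
#'
#' Concatenates the trials of the requested periods with an inter-trial
#' rest gap, plus leading and trailing rest, producing the
#' ground-truth kinematics a participant mimics.
#'
#' @param schedule a `schedule`.
#' @param periods character vector of period labels to include (default
#'   all).
#' @param frame_rate frames per second (default 30).
#' @param rest_gap_s rest inserted before, between and after trials
#'   (default 2 s; the protocol's wall-clock period lengths imply
#'   substantial inter-trial rest but do not print its value).
#' @return A [kinematic_trace()] with trial boundaries and per-trial info.
#' @export
gen_schedule_kinematics <- function(schedule, periods = NULL,
                                    frame_rate = 30, rest_gap_s = 2) {
  if (!inherits(schedule, "schedule")) abort_config("schedule required")
  trials <- schedule$trials
  if (!is.null(periods))
    trials <- Filter(function(tr) tr$period %in% periods, trials)
  if (!length(trials)) abort_config("no trials in the requested periods")
  gap <- matrix(0, length(schedule$dof_names),
                max(0L, round(rest_gap_s * frame_rate)))
  segs <- list(gap)
  starts <- integer(); infos <- list()
  cursor <- ncol(gap)
  for (tr in trials) {
    tt <- if (inherits(tr$move, "combination_spec"))
      gen_combination_trial(tr$move, frame_rate, schedule$dof_names)
    else gen_individual_trial(tr$move, frame_rate, schedule$dof_names)
    segs[[length(segs) + 1L]] <- tt$positions
    starts <- c(starts, cursor + 1L)
    infos[[length(infos) + 1L]] <-
      data.frame(label = tr$move$label, period = tr$period, rep = tr$rep,
                 start_frame = cursor + 1L,
                 end_frame = cursor + ncol(tt$positions))
    cursor <- cursor + ncol(tt$positions) + ncol(gap)
    segs[[length(segs) + 1L]] <- gap
  }
  pos <- do.call(cbind, segs)
  kinematic_trace(pos, frame_rate, schedule$dof_names,
                  trial_boundaries = starts,
                  trial_info = do.call(rbind, infos))
}

#' Read / write kinematic traces as wide CSV
#'
#' Wide format: `time_s` plus one column per DOF.
#' @param path CSV file path.
#' @param frame_rate frames/s; inferred from `time_s` when `NULL`.
#' @return `read_kinematic_csv`: a [kinematic_trace()].
#' @export
read_kinematic_csv <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") abort_data("first column must be time_s")
  if (is.null(frame_rate)) {
    if (nrow(df) < 2) abort_data("cannot infer frame rate")
    frame_rate <- 1 / stats::median(diff(df[[1]]))
  }
  kinematic_trace(t(as.matrix(df[, -1, drop = FALSE])), frame_rate,
                  dof_names = names(df)[-1])
}

#' @rdname read_kinematic_csv
#' @param trace a [kinematic_trace()].
#' @export
write_kinematic_csv <- function(trace, path) {
  df <- data.frame(time_s = (seq_len(ncol(trace$positions)) - 1) /
                     trace$frame_rate,
                   t(trace$positions), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(trace)
}

#' Serialize a schedule to JSON
#' @param schedule a `schedule`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  enc_move <- function(m) {
    if (inherits(m, "combination_spec"))
      list(type = "combination", primary = enc_move(m$primary),
           secondary = enc_move(m$secondary),
           secondary_delay_s = m$secondary_delay_s)
    else list(type = "individual", dof = m$dof, direction = m$direction,
              amplitude = m$amplitude, rise_s = m$rise_s, hold_s = m$hold_s,
              fall_s = m$fall_s, label = m$label)
  }
  obj <- list(phase = schedule$phase, dof_names = schedule$dof_names,
              trials = lapply(schedule$trials, function(tr)
                list(move = enc_move(tr$move), rep = tr$rep,
                     period = tr$period)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
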