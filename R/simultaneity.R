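#' Simultaneity analysis configuration
#'
#' Thresholds defining "active" movement in a decoded two-DOF trace,
#' chosen from the movement ranges a pick-and-rotate task actually
#' requires: the wrist must rotate at least 35% of its window (either
#' direction) and the hand must close at least 20% of its window
#' (closing direction only — holding requires closure). Simultaneous
#' bouts shorter than `min_bout_s` (1 s) are excluded as sporadic
#' predictions.
#'
#' @param wrist_threshold fraction of the wrist window (default 0.35).
#' @param hand_threshold fraction of the hand window (default 0.20).
#' @param min_bout_s minimum simultaneous-bout duration in s (default 1).
#' @return An object of class `simultaneity_config`.
#' @export
simultaneity_config <- function(wrist_threshold = 0.35,
                                hand_threshold = 0.20, min_bout_s = 1) {
  if (wrist_threshold <= 0 || wrist_threshold >= 1 ||
      hand_threshold <= 0 || hand_threshold >= 1)
    abort_config("thresholds must lie in (0, 1)")
  if (min_bout_s < 0) abort_config("min_bout_s must be >= 0")
  structure(list(wrist_threshold = wrist_threshold,
                 hand_threshold = hand_threshold,
                 min_bout_s = min_bout_s),
            class = "simultaneity_config")
}

#' Proportion of simultaneously active movement time
#'
#' Fraction of active time during which the hand and wrist move
#' simultaneously: frames where both DOFs exceed their activity
#' thresholds are grouped into contiguous bouts, bouts shorter than the
#' minimum duration are discarded, and the retained simultaneous time is
#' divided by the time either DOF is active (the denominator is not
#' bout-filtered). If neither DOF is ever active the proportion is 0
#' with `no_activity = TRUE`.
#'
#' @param trace a decoded [kinematic_trace()] containing the hand and
#'   wrist DOFs.
#' @param config a [simultaneity_config()].
#' @param hand_dof,wrist_dof names of the hand-closure and
#'   wrist-rotation DOFs in the trace.
#' @return A `simultaneity_result`: `proportion`, `bouts` (data.frame of
#'   start_s/end_s), `active_time_s`, `simultaneous_time_s`,
#'   `no_activity`.
#' @export
simultaneous_proportion <- function(trace, config = simultaneity_config(),
                                    hand_dof = "hand",
                                    wrist_dof = "wrist") {
  if (!all(c(hand_dof, wrist_dof) %in% trace$dof_names))
    abort_config("trace lacks DOFs '", hand_dof, "' / '", wrist_dof, "'")
  fr <- trace$frame_rate
  hand <- trace$positions[hand_dof, ]
  wrist <- trace$positions[wrist_dof, ]
  hand_active <- hand >= config$hand_threshold       # closing only
  wrist_active <- abs(wrist) >= config$wrist_threshold
  active <- hand_active | wrist_active
  simult <- hand_active & wrist_active
  min_frames <- ceiling(config$min_bout_s * fr)
  r <- rle(simult)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  bouts <- data.frame(start_s = (starts[keep] - 1) / fr,
                      end_s = ends[keep] / fr)
  simultaneous_time <- sum(r$lengths[keep]) / fr
  active_time <- sum(active) / fr
  structure(
    list(proportion = if (active_time > 0)
           simultaneous_time / active_time else 0,
         bouts = bouts,
         active_time_s = active_time,
         simultaneous_time_s = simultaneous_time,
         no_activity = active_time == 0),
    class = "simultaneity_result")
}

#' @export
print.simultaneity_result <- function(x, ...) {
  cat(sprintf("<simultaneity_result> %.1f%% of %.1f s active time simultaneous (%d bout(s))\n",
              100 * x$proportion, x$active_time_s, nrow(x$bouts)))
  invisible(x)
}

#' Compare simultaneity across decoder algorithms
#'
#' Takes per-participant median simultaneity proportions per algorithm,
#' records a Shapiro-Wilk normality check per group, runs a one-way
#' ANOVA across algorithms and, when the ANOVA is significant, Tukey's
#' Honestly Significant Difference pairwise comparisons. The named tests
#' are delegated to the standard implementations.
#'
#' @param medians data.frame with columns `participant`, `algorithm`,
#'   `value` (one median per participant per algorithm).
#' @param alpha significance level (default 0.05).
#' @return A list report: `shapiro` (per-group p-values), `anova_p`,
#'   `tukey` (pairwise table), `significant_pairs`.
#' @export
compare_simultaneity <- function(medians, alpha = 0.05) {
  need <- c("participant", "algorithm", "value")
  if (!all(need %in% names(medians)))
    abort_config("medians needs columns participant, algorithm, value")
  medians$algorithm <- factor(medians$algorithm)
  if (nlevels(medians$algorithm) < 2) abort_data("need >= 2 algorithms")
  if (min(table(medians$algorithm)) < 2)
    abort_data("need >= 2 observations per algorithm")
  shapiro <- vapply(split(medians$value, medians$algorithm), function(v) {
    if (length(unique(v)) < 3) NA_real_ else stats::shapiro.test(v)$p.value
  }, numeric(1))
  fit <- stats::aov(value ~ algorithm, data = medians)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey <- NULL; significant_pairs <- character()
  if (is.finite(anova_p) && anova_p < alpha) {
    tk <- stats::TukeyHSD(fit)$algorithm
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
    significant_pairs <- tukey$pair[tukey$p_adj < alpha]
  }
  list(test = "anova_tukey", alpha = alpha, shapiro = shapiro,
       anova_p = anova_p, tukey = tukey,
       significant_pairs = significant_pairs,
       n_per_group = as.vector(table(medians$algorithm)))
}
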