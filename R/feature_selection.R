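#' Temporal alignment of features to kinematics
#'
#' Mimicry training assumes the user tracks the prosthesis exactly, but
#' muscle activity leads or lags the programmed kinematics by a roughly
#' constant electromechanical offset. `align_lag` scans candidate lags
#' and returns the one maximizing the mean absolute Pearson correlation
#' over every (feature, DOF) pair. Positive lag means the kinematics
#' trail the features by that many frames (the usual case: EMG leads).
#' Ties break toward smaller |lag|, then toward the negative lag.
#'
#' @param features a [feature_series()].
#' @param kinematics a [kinematic_trace()] at the same frame rate.
#' @param max_lag_frames scan range (default 15 frames, about 0.5 s).
#' @return An `alignment_result`: `lag_frames` and
#'   `mean_abs_correlation` at that lag.
#' @export
align_lag <- function(features, kinematics, max_lag_frames = 15) {
  F <- features$values; K <- kinematics$positions
  n <- ncol(F)
  if (ncol(K) != n) abort_config("frame counts differ")
  if (abs(features$frame_rate - kinematics$frame_rate) >
      1e-6 * features$frame_rate)
    abort_config("frame rates differ")
  if (max_lag_frames >= n - 2) abort_config("max_lag_frames too large")
  lags <- seq(-max_lag_frames, max_lag_frames)
  lags <- lags[order(abs(lags), lags)]  # tie-break order
  best <- NULL
  for (L in lags) {
    if (L >= 0) { fi <- seq_len(n - L); ki <- fi + L }
    else { ki <- seq_len(n + L); fi <- ki - L }
    cm <- suppressWarnings(
      stats::cor(t(F[, fi, drop = FALSE]), t(K[, ki, drop = FALSE])))
    score <- mean(abs(cm), na.rm = TRUE)
    if (is.nan(score)) next
    if (is.null(best) || score > best$mean_abs_correlation + 1e-12)
      best <- list(lag_frames = L, mean_abs_correlation = score)
  }
  if (is.null(best))
    abort_data("all feature/DOF pairs are degenerate; cannot align")
  structure(best, class = "alignment_result")
}

#' Apply a chosen lag to a training set
#'
#' Shifts the kinematics by `lag_frames` (positive = kinematics trail
#' the features) and trims the non-overlapping frames; trial bookkeeping
#' follows the kinematics.
#'
#' @param train a [training_set()].
#' @param lag_frames signed integer lag, e.g. from [align_lag()].
#' @return The aligned [training_set()].
#' @export
apply_alignment <- function(train, lag_frames) {
  n <- ncol(train$features$values)
  L <- as.integer(lag_frames)
  if (abs(L) >= n) abort_config("lag exceeds series length")
  if (L >= 0) { fi <- seq_len(n - L); ki <- fi + L }
  else { ki <- seq_len(n + L); fi <- ki - L }
  feats <- train$features
  feats$values <- feats$values[, fi, drop = FALSE]
  feats$warmup <- feats$warmup[fi]
  feats$frame_times <- feats$frame_times[fi]
  kin <- train$kinematics
  kin$positions <- kin$positions[, ki, drop = FALSE]
  kin$trial_boundaries <- pmax(kin$trial_boundaries - max(L, 0L), 1L)
  training_set(feats, kin, train$trial_frames[ki], train$trial_info)
}

#' Stepwise Gram-Schmidt feature selection
#'
#' Greedy forward selection of `k` features for the Kalman and MLP
#' decoders. At each step the candidate whose component orthogonal to
#' the span of the already-selected features has the largest summed
#' squared correlation with the kinematic DOFs is selected, and that
#' component is orthogonalized out of all remaining candidates. Features
#' are mean-centered over the training frames first, so the criterion is
#' scale-free.
#'
#' @param features a [feature_series()] (aligned to the kinematics).
#' @param kinematics the paired [kinematic_trace()].
#' @param k number of features to select (default 48).
#' @return A `selection_result`: `selected_indices` (ordered),
#'   `selected_names`, and per-step `scores`.
#' @export
gram_schmidt_select <- function(features, kinematics, k = 48) {
  if (k <= 0) abort_config("k must be positive")
  F <- t(features$values)              # frames x p
  Y <- t(kinematics$positions)         # frames x d
  if (nrow(F) != nrow(Y)) abort_config("frame counts differ")
  p <- ncol(F)
  if (k > p) abort_config("k exceeds the number of features")
  F <- scale(F, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  ynorm <- sqrt(colSums(Y^2))
  ok_y <- ynorm > 1e-12
  if (!any(ok_y)) abort_data("all kinematic DOFs are constant")
  Y <- Y[, ok_y, drop = FALSE]; ynorm <- ynorm[ok_y]
  R <- F                                # residual candidates
  selected <- integer(); scores <- numeric()
  tol <- 1e-10 * max(sqrt(colSums(F^2)), 1)
  for (step in seq_len(k)) {
    rnorm_ <- sqrt(colSums(R^2))
    avail <- setdiff(which(rnorm_ > tol), selected)
    if (!length(avail)) {
      warning("residual features exhausted; selected ", length(selected),
              " of ", k, " features")
      break
    }
    cors <- crossprod(R[, avail, drop = FALSE], Y) /
      outer(rnorm_[avail], ynorm)
    sc <- rowSums(cors^2)
    pick <- avail[which.max(sc)]
    selected <- c(selected, pick)
    scores <- c(scores, max(sc))
    u <- R[, pick] / rnorm_[pick]
    R <- R - outer(u, as.vector(crossprod(u, R)))
    R[, pick] <- 0
  }
  structure(
    list(selected_indices = selected,
         selected_names = features$feature_names[selected],
         scores = scores),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s) selected\n",
              length(x$selected_indices)))
  invisible(x)
}

#' Restrict a training set or feature series to selected features
#' @param x a [training_set()] or [feature_series()].
#' @param selection a `selection_result` or integer index vector.
#' @return Object of the same class with only the selected feature rows.
#' @export
select_features <- function(x, selection) {
  idx <- if (inherits(selection, "selection_result"))
    selection$selected_indices else as.integer(selection)
  if (inherits(x, "training_set")) {
    x$features$values <- x$features$values[idx, , drop = FALSE]
    x$features$feature_names <- x$features$feature_names[idx]
    x
  } else if (inherits(x, "feature_series")) {
    x$values <- x$values[idx, , drop = FALSE]
    x$feature_names <- x$feature_names[idx]
    x
  } else abort_config("x must be a training_set or feature_series")
}
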