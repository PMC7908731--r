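#' Fit the linear Kalman decoder
#'
#' Fits the standard neural-decoding Kalman filter: a random-walk-like
#' state model on the kinematics, `x[t+1] = A x[t] + w`, and a linear
#' observation model of the EMG features on the kinematics,
#' `z[t] = C x[t] + q`, both by least squares over all training frames
#' (no train/validation split). `A`/`W` come from successive kinematic
#' frames; `C`/`Q` from regressing features on kinematics. Rank-deficient
#' normal equations fall back to a small ridge with a warning.
#'
#' @param train a [training_set()], its features already restricted to
#'   the selected subset (see [select_features()]).
#' @param ridge ridge constant used only on rank deficiency.
#' @return A `kalman_model`: matrices `A`, `W`, `C`, `Q`, per-DOF
#'   `thresholds` (initially 0) and the feature names used.
#' @export
fit_kalman <- function(train, ridge = 1e-8) {
  X <- train$kinematics$positions   # d x T
  Z <- train$features$values        # p x T
  n <- ncol(X)
  if (n < 2) abort_data("need at least 2 frames to fit")
  X1 <- X[, -n, drop = FALSE]; X2 <- X[, -1, drop = FALSE]
  A <- ls_solve(X2, X1, ridge)
  resA <- X2 - A %*% X1
  W <- tcrossprod(resA) / max(1, n - 2)
  C <- ls_solve(Z, X, ridge)
  resC <- Z - C %*% X
  Q <- tcrossprod(resC) / max(1, n - 1)
  structure(
    list(A = A, W = symmetrize(W), C = C, Q = symmetrize(Q),
         thresholds = stats::setNames(rep(0, nrow(X)),
                                      train$kinematics$dof_names),
         feature_names = train$features$feature_names,
         dof_names = train$kinematics$dof_names),
    class = "kalman_model")
}

# least squares B minimizing ||Y - B X||: B = Y X' (X X')^{-1}
ls_solve <- function(Y, X, ridge) {
  G <- tcrossprod(X)
  B <- try(t(solve(G, tcrossprod(X, Y))), silent = TRUE)
  if (inherits(B, "try-error") || rcond_safe(G) < 1e-12) {
    warning("rank-deficient regressors; using ridge fallback")
    G <- G + diag(ridge * max(diag(G), 1), nrow(G))
    B <- t(solve(G, tcrossprod(X, Y)))
  }
  B
}

rcond_safe <- function(G) tryCatch(rcond(G), error = function(e) 0)

symmetrize <- function(M) (M + t(M)) / 2

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model> %d feature(s) -> %d DOF; thresholds: %s\n",
              nrow(x$C), ncol(x$C),
              paste(sprintf("%.2f", x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Initial decoder state (rest, identity covariance)
#' @param model a `kalman_model`.
#' @return A `decode_state` with `x = 0`, `P = I`.
#' @export
kalman_init <- function(model) {
  d <- ncol(model$C)
  structure(list(x = rep(0, d), P = diag(d)), class = "decode_state")
}

#' One Kalman predict/update cycle
#'
#' Standard recursion: predict through `A`/`W`, then update against the
#' observed feature frame through `C`/`Q`. The covariance is symmetrized
#' each step; the raw estimate is clamped to [-1, 1] (position commands).
#'
#' @param model a `kalman_model`.
#' @param state a `decode_state` from [kalman_init()] or a previous step.
#' @param feature_frame numeric feature vector for this frame.
#' @return `list(state = <decode_state>, raw_estimate = <vector>)`.
#' @export
kalman_step <- function(model, state, feature_frame) {
  if (!all(is.finite(feature_frame))) abort_data("non-finite feature frame")
  xp <- model$A %*% state$x
  Pp <- symmetrize(model$A %*% state$P %*% t(model$A) + model$W)
  S <- model$C %*% Pp %*% t(model$C) + model$Q
  # Pp C' S^{-1}; a noiseless Q can leave S rank-deficient, so fall back
  # to a minimally regularized solve
  K <- t(tryCatch(solve(S, model$C %*% Pp), error = function(e)
    solve(S + diag(1e-10 * max(diag(S), 1), nrow(S)),
          model$C %*% Pp)))
  x <- xp + K %*% (feature_frame - model$C %*% xp)
  P <- symmetrize((diag(length(x)) - K %*% model$C) %*% Pp)
  list(state = structure(list(x = as.vector(x), P = P),
                         class = "decode_state"),
       raw_estimate = clamp(as.vector(x)))
}

#' Dead-zone output thresholds
#'
#' The "modification" of the modified Kalman filter: per-DOF dead zones
#' that suppress small outputs (rest jitter) and rescale the remainder
#' so full scale stays reachable:
#' `|v| <= thr -> 0`, else `sign(v) (|v| - thr) / (1 - thr)`.
#' The map is continuous in `v` and the identity at `thr = 0`.
#'
#' @param raw_estimate numeric vector (or DOF x frames matrix) in [-1, 1].
#' @param thresholds per-DOF thresholds in [0, 1).
#' @return Thresholded values, same shape as the input.
#' @export
apply_thresholds <- function(raw_estimate, thresholds) {
  if (any(thresholds < 0 | thresholds >= 1))
    abort_config("thresholds must lie in [0, 1)")
  f <- function(v, thr) sign(v) * pmax(abs(v) - thr, 0) / (1 - thr)
  if (is.matrix(raw_estimate)) {
    out <- raw_estimate
    for (i in seq_len(nrow(out))) out[i, ] <- f(raw_estimate[i, ],
                                                thresholds[i])
    out
  } else f(raw_estimate, thresholds)
}

#' Offline per-DOF threshold optimization
#'
#' Runs the fitted Kalman decoder over the full training set once, then
#' for each DOF independently picks the grid threshold minimizing the
#' mean squared error between the thresholded output and the training
#' kinematics (all training data; no validation split). Ties go to the
#' smaller threshold.
#'
#' @param model a fitted `kalman_model`.
#' @param train the [training_set()] used for fitting.
#' @param grid candidate thresholds (default 0 to 0.5 by 0.02).
#' @return The model with `thresholds` set to the optimum (the chosen
#'   vector is also attached as attribute `"mse"`-annotated vector in
#'   `model$threshold_search`).
#' @export
optimize_thresholds <- function(model, train, grid = seq(0, 0.5, by = 0.02)) {
  if (!length(grid)) abort_config("threshold grid is empty")
  if (any(grid < 0 | grid >= 1)) abort_config("grid values must lie in [0, 1)")
  raw <- predict_stream(model, train$features, raw = TRUE)
  truth <- train$kinematics$positions
  d <- nrow(truth)
  thr <- numeric(d)
  mse <- matrix(NA_real_, d, length(grid))
  for (i in seq_len(d)) {
    v <- raw$positions[i, ]
    for (j in seq_along(grid)) {
      out <- sign(v) * pmax(abs(v) - grid[j], 0) / (1 - grid[j])
      mse[i, j] <- mean((out - truth[i, ])^2)
    }
    thr[i] <- grid[which.min(mse[i, ])]
  }
  model$thresholds <- stats::setNames(thr, model$dof_names)
  model$threshold_search <- list(grid = grid, mse = mse)
  model
}

#' Decode a feature stream into kinematics
#'
#' Shared predict contract for all decoders: frame-synchronous kinematic
#' estimates in [-1, 1], one output frame per input frame.
#'
#' @param model a `kalman_model`, `mlp_model` or `cnn_model`.
#' @param features a [feature_series()] whose rows match the features
#'   the model was trained on.
#' @param ... method-specific options (`raw = TRUE` on the Kalman method
#'   skips the output thresholds).
#' @return A [kinematic_trace()].
#' @export
predict_stream <- function(model, features, ...) UseMethod("predict_stream")

#' @rdname predict_stream
#' @param raw skip the per-DOF dead-zone thresholds.
#' @export
predict_stream.kalman_model <- function(model, features, raw = FALSE, ...) {
  Z <- features$values
  if (nrow(Z) != nrow(model$C))
    abort_config("feature dimensionality does not match the model")
  state <- kalman_init(model)
  d <- ncol(model$C)
  out <- matrix(0, d, ncol(Z), dimnames = list(model$dof_names, NULL))
  for (t in seq_len(ncol(Z))) {
    st <- kalman_step(model, state, Z[, t])
    state <- st$state
    out[, t] <- st$raw_estimate
  }
  if (!raw) out <- apply_thresholds(out, model$thresholds)
  kinematic_trace(out, features$frame_rate, model$dof_names)
}

#' Serialize a Kalman model to JSON
#' @param model a `kalman_model`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_kalman_json <- function(model, path) {
  obj <- list(type = "kalman", version = 1L,
              dof_names = model$dof_names,
              feature_names = model$feature_names,
              A = model$A, W = model$W, C = model$C, Q = model$Q,
              thresholds = model$thresholds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_kalman_json
#' @export
read_kalman_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- function(x) matrix(as.numeric(x), nrow = nrow(x))
  structure(
    list(A = m(obj$A), W = m(obj$W), C = m(obj$C), Q = m(obj$Q),
         thresholds = stats::setNames(as.numeric(obj$thresholds),
                                      obj$dof_names),
         feature_names = obj$feature_names, dof_names = obj$dof_names),
    class = "kalman_model")
}
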