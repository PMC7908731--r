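#' Fit the temporal convolutional network decoder
#'
#' An eight-layer network regressing the DOF positions from a trailing
#' window of the full feature stream (no feature selection): temporal
#' convolution (kernel 5, 64 filters) -> tanh -> temporal convolution
#' (kernel 3, 32 filters) -> tanh -> flatten -> dense 128 -> tanh ->
#' dense DOF. Each prediction sees the last `window` frames (default 15,
#' about half a second), so the network is causal in the feature stream.
#' Data are split 75/25 by trial; training uses mean squared error with
#' Adam and stops when the validation loss has been equal to or larger
#' than the previously smallest loss for `patience` (5) consecutive
#' epochs, with a `max_epochs` backstop. Inputs are scaled by the
#' train-split maximum. Deterministic given (data, seed).
#'
#' @param train a [training_set()] with the full feature set.
#' @param seed integer seed controlling init, split and shuffling.
#' @param window trailing frames per prediction (default 15).
#' @param filters conv filter counts, fixed `c(64, 32)`.
#' @param kernels conv kernel widths, fixed `c(5, 3)`.
#' @param dense width of the dense layer (128).
#' @param max_epochs early-stopping backstop (default 200).
#' @param patience consecutive non-improving validation epochs (5).
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @return `list(model = <cnn_model>, report = <train_report>)`.
#' @export
fit_cnn <- function(train, seed = 1, window = 15,
                    filters = c(64, 32), kernels = c(5, 3), dense = 128,
                    max_epochs = 200, patience = 5,
                    lr = 1e-3, batch_size = 64) {
  Xs <- train$features$values            # p x T
  Y_all <- t(train$kinematics$positions) # T x d
  p <- nrow(Xs); Tn <- ncol(Xs); d <- ncol(Y_all)
  trial_len <- vapply(trial_frame_ranges(train), length, integer(1))
  if (length(trial_len) && min(trial_len) < window)
    abort_config("window is longer than the shortest trial")
  if (Tn < window + 1) abort_data("recording shorter than one window")
  sp <- split_by_trial(train$trial_frames, 0.75, seed)
  scale_ <- max(abs(Xs[, sp$train[sp$train <= Tn], drop = FALSE]), 1e-8)
  Xs <- Xs / scale_
  samples <- seq(window, Tn)
  tr_s <- samples[samples %in% sp$train]
  va_s <- samples[samples %in% sp$val]
  if (!length(va_s)) abort_data("validation split is empty")
  n1 <- window - kernels[1] + 1
  n2 <- n1 - kernels[2] + 1
  params <- with_seed(seed, list(
    W1 = glorot(p * kernels[1], filters[1]), b1 = numeric(filters[1]),
    W2 = glorot(filters[1] * kernels[2], filters[2]),
    b2 = numeric(filters[2]),
    W3 = glorot(n2 * filters[2], dense), b3 = numeric(dense),
    W4 = glorot(dense, d), b4 = numeric(d)))
  geom <- list(window = window, k1 = kernels[1], k2 = kernels[2],
               n1 = n1, n2 = n2, f1 = filters[1], f2 = filters[2])
  opt <- adam_init(params)
  tr_loss <- c(); va_loss <- c()
  best <- Inf; streak <- 0L; stop_reason <- "max_epochs"
  for (ep in seq_len(max_epochs)) {
    idx <- with_seed(seed + ep, sample(tr_s))
    for (start in seq(1, length(idx), by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1, length(idx))]
      g <- cnn_grad(params, geom, Xs, b, Y_all[b, , drop = FALSE])
      upd <- adam_update(params, g, opt, lr = lr)
      params <- upd$params; opt <- upd$state
    }
    tr_loss <- c(tr_loss, cnn_loss(params, geom, Xs, tr_s, Y_all))
    va <- cnn_loss(params, geom, Xs, va_s, Y_all)
    va_loss <- c(va_loss, va)
    if (va < best) {
      best <- va; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) { stop_reason <- "early_stop"; break }
    }
  }
  model <- structure(
    list(params = params, geom = geom, scale = scale_,
         input_dim = p, output_dim = d, seed = seed,
         dof_names = train$kinematics$dof_names,
         feature_names = train$features$feature_names),
    class = "cnn_model")
  list(model = model,
       report = new_train_report(c(train = 0.75, validation = 0.25),
                                 tr_loss, va_loss, stop_reason))
}

# im2col over trailing windows ending at stream frames tt
cnn_forward <- function(params, geom, Xs, tt) {
  B <- length(tt); p <- nrow(Xs)
  base1 <- rep(tt, each = geom$n1) - geom$window + rep(seq_len(geom$n1), B)
  P1 <- matrix(0, B * geom$n1, p * geom$k1)
  for (k in seq_len(geom$k1))
    P1[, (k - 1) * p + seq_len(p)] <- t(Xs[, base1 + k - 1, drop = FALSE])
  A1 <- tanh(sweep(P1 %*% params$W1, 2, params$b1, "+"))
  idx2 <- lapply(seq_len(geom$k2), function(k)
    rep((seq_len(B) - 1) * geom$n1, each = geom$n2) +
      rep(seq_len(geom$n2), B) + k - 1)
  P2 <- do.call(cbind, lapply(idx2, function(ix) A1[ix, , drop = FALSE]))
  A2 <- tanh(sweep(P2 %*% params$W2, 2, params$b2, "+"))
  Fl <- matrix(as.vector(t(A2)), nrow = B, byrow = TRUE)
  H <- tanh(sweep(Fl %*% params$W3, 2, params$b3, "+"))
  Y <- sweep(H %*% params$W4, 2, params$b4, "+")
  list(P1 = P1, A1 = A1, idx2 = idx2, P2 = P2, A2 = A2, Fl = Fl,
       H = H, Y = Y)
}

cnn_loss <- function(params, geom, Xs, tt, Y_all, chunk = 1024L) {
  tot <- 0; n <- 0
  for (start in seq(1, length(tt), by = chunk)) {
    b <- tt[start:min(start + chunk - 1, length(tt))]
    f <- cnn_forward(params, geom, Xs, b)
    tot <- tot + sum((f$Y - Y_all[b, , drop = FALSE])^2)
    n <- n + length(b) * ncol(Y_all)
  }
  tot / n
}

cnn_grad <- function(params, geom, Xs, tt, Y) {
  f <- cnn_forward(params, geom, Xs, tt)
  B <- length(tt)
  dY <- 2 * (f$Y - Y) / length(Y)
  dW4 <- crossprod(f$H, dY); db4 <- colSums(dY)
  dH <- tcrossprod(dY, params$W4) * (1 - f$H^2)
  dW3 <- crossprod(f$Fl, dH); db3 <- colSums(dH)
  dFl <- tcrossprod(dH, params$W3)
  dA2 <- matrix(as.vector(t(dFl)), ncol = geom$f2, byrow = TRUE) *
    (1 - f$A2^2)
  dW2 <- crossprod(f$P2, dA2); db2 <- colSums(dA2)
  dP2 <- tcrossprod(dA2, params$W2)
  dA1 <- matrix(0, B * geom$n1, geom$f1)
  for (k in seq_len(geom$k2)) {
    cols <- (k - 1) * geom$f1 + seq_len(geom$f1)
    ix <- f$idx2[[k]]
    dA1[ix, ] <- dA1[ix, , drop = FALSE] + dP2[, cols, drop = FALSE]
  }
  dZ1 <- dA1 * (1 - f$A1^2)
  dW1 <- crossprod(f$P1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

#' @export
print.cnn_model <- function(x, ...) {
  g <- x$geom
  cat(sprintf(
    "<cnn_model> %d feature(s) x %d-frame window: conv%d(%d) -> conv%d(%d) -> dense %d -> %d DOF, seed %d\n",
    x$input_dim, g$window, g$k1, g$f1, g$k2, g$f2,
    ncol(x$params$W3), x$output_dim, x$seed))
  invisible(x)
}

#' @rdname predict_stream
#' @export
predict_stream.cnn_model <- function(model, features, ...) {
  Xs <- features$values
  if (nrow(Xs) != model$input_dim)
    abort_config("feature dimensionality does not match the model")
  Xs <- Xs / model$scale
  Tn <- ncol(Xs); W <- model$geom$window
  out <- matrix(0, model$output_dim, Tn,
                dimnames = list(model$dof_names, NULL))
  if (Tn >= W) {
    tt <- seq(W, Tn)
    for (start in seq(1, length(tt), by = 1024L)) {
      b <- tt[start:min(start + 1023L, length(tt))]
      out[, b] <- t(cnn_forward(model$params, model$geom, Xs, b)$Y)
    }
  }
  kinematic_trace(clamp(out), features$frame_rate, model$dof_names)
}
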