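#' Fit the multilayer-perceptron decoder
#'
#' A fully connected regression network mapping one frame of selected
#' features to the DOF positions: two hidden layers of 128 units with
#' hyperbolic-tangent activations and a linear output, trained on mean
#' squared error with Adam (learning rate 1e-3, batch 64). Training runs
#' three dataset-aggregation iterations of ten epochs each; each outer
#' iteration re-shuffles and re-concatenates the training set (offline
#' stand-in for aggregation of newly collected data — `aggregate_fn`
#' is the hook where online data could be injected). The data are split
#' 80/20 by trial; the 20% split is monitored, not used for stopping.
#' Inputs are standardized with train-split means and variances.
#' Deterministic given (data, seed).
#'
#' @param train a [training_set()] restricted to the selected features.
#' @param seed integer seed controlling init, split and shuffling.
#' @param hidden hidden-layer widths (fixed architecture, default
#'   `c(128, 128)`).
#' @param iterations,epochs_per_iteration the 3 x 10 training schedule.
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param aggregate_fn optional `function(train_set, iteration)` returning
#'   a training_set with extra aggregated data for the next iteration.
#' @return `list(model = <mlp_model>, report = <train_report>)`.
#' @export
fit_mlp <- function(train, seed = 1, hidden = c(128, 128),
                    iterations = 3, epochs_per_iteration = 10,
                    lr = 1e-3, batch_size = 64, aggregate_fn = NULL) {
  X_all <- t(train$features$values)       # frames x p
  Y_all <- t(train$kinematics$positions)  # frames x d
  sp <- split_by_trial(train$trial_frames, 0.8, seed)
  mu <- colMeans(X_all[sp$train, , drop = FALSE])
  sd_ <- pmax(apply(X_all[sp$train, , drop = FALSE], 2, stats::sd), 1e-8)
  X_all <- sweep(sweep(X_all, 2, mu), 2, sd_, "/")
  p <- ncol(X_all); d <- ncol(Y_all)
  params <- with_seed(seed, list(
    W1 = glorot(p, hidden[1]), b1 = numeric(hidden[1]),
    W2 = glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = glorot(hidden[2], d), b3 = numeric(d)))
  opt <- adam_init(params)
  tr_loss <- c(); va_loss <- c()
  idx_train <- sp$train
  for (it in seq_len(iterations)) {
    if (it > 1 && !is.null(aggregate_fn)) {
      train <- aggregate_fn(train, it)
      X_all <- sweep(sweep(t(train$features$values), 2, mu), 2, sd_, "/")
      Y_all <- t(train$kinematics$positions)
      idx_train <- split_by_trial(train$trial_frames, 0.8, seed)$train
    }
    # re-shuffle / re-concatenate the training frames for this iteration
    idx <- with_seed(seed + 1000L * it, sample(idx_train))
    for (ep in seq_len(epochs_per_iteration)) {
      idx <- with_seed(seed + 1000L * it + ep, sample(idx))
      for (start in seq(1, length(idx), by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1, length(idx))]
        g <- mlp_grad(params, X_all[b, , drop = FALSE],
                      Y_all[b, , drop = FALSE])
        upd <- adam_update(params, g, opt, lr = lr)
        params <- upd$params; opt <- upd$state
      }
      tr_loss <- c(tr_loss, mlp_loss(params, X_all[idx_train, , drop = FALSE],
                                     Y_all[idx_train, , drop = FALSE]))
      va_loss <- c(va_loss,
                   if (length(sp$val))
                     mlp_loss(params, X_all[sp$val, , drop = FALSE],
                              Y_all[sp$val, , drop = FALSE]) else NA_real_)
    }
  }
  model <- structure(
    list(params = params, mu = mu, sd = sd_, hidden = hidden,
         input_dim = p, output_dim = d, seed = seed,
         dof_names = train$kinematics$dof_names,
         feature_names = train$features$feature_names),
    class = "mlp_model")
  list(model = model,
       report = new_train_report(c(train = 0.8, validation = 0.2),
                                 tr_loss, va_loss, "max_epochs"))
}

mlp_forward <- function(params, X) {
  H1 <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
  H2 <- tanh(sweep(H1 %*% params$W2, 2, params$b2, "+"))
  Y <- sweep(H2 %*% params$W3, 2, params$b3, "+")
  list(H1 = H1, H2 = H2, Y = Y)
}

mlp_loss <- function(params, X, Y) {
  mean((mlp_forward(params, X)$Y - Y)^2)
}

mlp_grad <- function(params, X, Y) {
  f <- mlp_forward(params, X)
  n <- length(Y)
  dY <- 2 * (f$Y - Y) / n
  dW3 <- crossprod(f$H2, dY); db3 <- colSums(dY)
  dH2 <- tcrossprod(dY, params$W3) * (1 - f$H2^2)
  dW2 <- crossprod(f$H1, dH2); db2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, params$W2) * (1 - f$H1^2)
  dW1 <- crossprod(X, dH1); db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d -> %s -> %d (tanh), seed %d\n",
              x$input_dim, paste(x$hidden, collapse = " -> "),
              x$output_dim, x$seed))
  invisible(x)
}

#' @rdname predict_stream
#' @export
predict_stream.mlp_model <- function(model, features, ...) {
  X <- t(features$values)
  if (ncol(X) != model$input_dim)
    abort_config("feature dimensionality does not match the model")
  X <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  Y <- mlp_forward(model$params, X)$Y
  kinematic_trace(clamp(t(Y)), features$frame_rate, model$dof_names)
}
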