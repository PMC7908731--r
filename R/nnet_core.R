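# Minimal vectorized neural-network machinery shared by the MLP and CNN
# decoders: seeded Glorot initialization, Adam, and the early-stopping
# rule. Everything is plain matrix algebra so training is deterministic
# given (data, seed) on a single thread.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Validation-loss early-stopping rule
#'
#' Training stops once the validation loss has been equal to or larger
#' than the previously smallest loss for `patience` consecutive epochs.
#' Given a full loss trace, returns the index of the last epoch that
#' would have been run, or `NA` if the rule never triggers.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated (default 5).
#' @return Integer epoch index at which training stops, or `NA`.
#' @export
early_stopping_epoch <- function(val_losses, patience = 5) {
  best <- Inf; streak <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(i)
    }
  }
  NA_integer_
}

# split trial ids into train/validation by trial (not by frame), seeded.
# Rest frames (trial 0) always train: they carry no movement to leak.
split_by_trial <- function(trial_frames, train_frac, seed) {
  ids <- setdiff(unique(trial_frames), 0L)
  if (length(ids) < 2) abort_data("need at least 2 trials to split")
  ord <- with_seed(seed, sample(ids))
  n_train <- max(1L, min(length(ids) - 1L,
                         round(train_frac * length(ids))))
  train_ids <- sort(ord[seq_len(n_train)])
  list(train = which(trial_frames %in% c(0L, train_ids)),
       val = which(!(trial_frames %in% c(0L, train_ids))),
       train_ids = train_ids,
       val_ids = sort(setdiff(ids, train_ids)))
}

new_train_report <- function(split_fractions, train_loss, val_loss,
                             stop_reason) {
  structure(
    list(split_fractions = split_fractions,
         epochs_run = length(train_loss),
         train_loss = train_loss, val_loss = val_loss,
         stop_reason = stop_reason),
    class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epoch(s), stop: %s, final train/val loss: %.4g / %.4g\n",
              x$epochs_run, x$stop_reason,
              utils::tail(x$train_loss, 1),
              utils::tail(x$val_loss, 1)))
  invisible(x)
}
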