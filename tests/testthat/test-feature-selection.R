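# Temporal alignment and Gram-Schmidt feature selection

make_pair <- function(n = 400, p = 6, d = 2, seed = 11) {
  set.seed(seed)
  kin <- smooth_kinematics(n, d, seed)
  W <- matrix(runif(p * d, -1, 1), p, d)
  feats <- feature_series(W %*% kin$positions +
                            0.02 * matrix(rnorm(p * n), p), 30)
  list(features = feats, kinematics = kin)
}

test_that("alignment recovers constructed shifts exactly", {
  pr <- make_pair()
  # perfectly aligned pair
  expect_equal(align_lag(pr$features, pr$kinematics)$lag_frames, 0)
  # delay the kinematics by 5 frames: positive lag by convention
  n <- ncol(pr$features$values)
  kin5 <- kinematic_trace(pr$kinematics$positions[, 1:(n - 5),
                                                  drop = FALSE],
                          30, pr$kinematics$dof_names)
  feat5 <- pr$features
  feat5$values <- feat5$values[, 6:n, drop = FALSE]
  feat5$warmup <- feat5$warmup[6:n]
  res <- align_lag(feat5, kin5)
  expect_equal(res$lag_frames, 5)
  # and the mirrored construction gives the negative lag
  kin_m <- kinematic_trace(pr$kinematics$positions[, 6:n, drop = FALSE],
                           30, pr$kinematics$dof_names)
  feat_m <- pr$features
  feat_m$values <- feat_m$values[, 1:(n - 5), drop = FALSE]
  feat_m$warmup <- feat_m$warmup[1:(n - 5)]
  expect_equal(align_lag(feat_m, kin_m)$lag_frames, -5)
})

test_that("alignment score equals an independent mean-|r| computation", {
  pr <- make_pair(seed = 21)
  res <- align_lag(pr$features, pr$kinematics, max_lag_frames = 10)
  L <- res$lag_frames
  n <- ncol(pr$features$values)
  fi <- if (L >= 0) 1:(n - L) else (1 - L):n
  ki <- fi + L
  oracle <- mean(abs(cor(t(pr$features$values[, fi, drop = FALSE]),
                         t(pr$kinematics$positions[, ki, drop = FALSE]))))
  expect_equal(res$mean_abs_correlation, oracle, tolerance = 1e-12)
})

test_that("degenerate series are excluded; all-degenerate errors", {
  pr <- make_pair()
  withcst <- pr$features
  withcst$values[1, ] <- 3  # constant feature excluded, not fatal
  expect_equal(align_lag(withcst, pr$kinematics)$lag_frames, 0)
  flat <- feature_series(matrix(1, 2, 100), 30)
  kin <- kinematic_trace(matrix(0, 1, 100), 30)
  expect_error(align_lag(flat, kin), class = "emgdec_data_error")
})

test_that("applying a lag trims frames and preserves pairing", {
  pr <- make_pair()
  ts <- training_set(pr$features, pr$kinematics)
  out <- apply_alignment(ts, 4)
  n <- ncol(pr$features$values)
  expect_equal(ncol(out$features$values), n - 4)
  expect_equal(out$kinematics$positions[, 1],
               pr$kinematics$positions[, 5], ignore_attr = TRUE)
  expect_equal(align_lag(out$features, out$kinematics,
                         max_lag_frames = 8)$lag_frames, -4)
})

test_that("first selected feature matches exhaustive single-feature search", {
  pr <- make_pair(p = 10, seed = 31)
  sel <- gram_schmidt_select(pr$features, pr$kinematics, k = 1)
  # brute force: summed squared correlation with the DOFs
  Y <- t(pr$kinematics$positions)
  sc <- apply(t(pr$features$values), 2,
              function(f) sum(cor(f, Y)^2))
  expect_equal(sel$selected_indices, unname(which.max(sc)))
  expect_equal(sel$scores, max(sc), tolerance = 1e-10)
})

test_that("greedy pair selection matches exhaustive search on easy geometry", {
  # near-orthogonal informative features make greedy provably optimal
  set.seed(41)
  n <- 500
  kin <- smooth_kinematics(n, 2, seed = 41)
  F <- matrix(rnorm(10 * n, sd = 1), 10)          # noise features
  F[3, ] <- kin$positions[1, ] + 0.01 * rnorm(n)  # DOF 1 carrier
  F[8, ] <- kin$positions[2, ] + 0.01 * rnorm(n)  # DOF 2 carrier
  feats <- feature_series(F, 30)
  sel <- gram_schmidt_select(feats, kin, k = 2)
  # exhaustive pair search: residual criterion evaluated for both orders
  Y <- scale(t(kin$positions), scale = FALSE)
  Fc <- scale(t(F), scale = FALSE)
  pair_score <- function(i, j) {
    s1 <- sum(cor(Fc[, i], Y)^2)
    u <- Fc[, i] / sqrt(sum(Fc[, i]^2))
    r <- Fc[, j] - u * sum(u * Fc[, j])
    s1 + sum(cor(r, Y)^2)
  }
  best <- -Inf; best_pair <- NULL
  for (i in 1:10) for (j in 1:10) if (i != j) {
    s <- pair_score(i, j)
    if (s > best) { best <- s; best_pair <- c(i, j) }
  }
  expect_setequal(sel$selected_indices, best_pair)
})

test_that("duplicated features are never selected twice", {
  pr <- make_pair(p = 5, seed = 51)
  dup <- pr$features
  dup$values <- rbind(dup$values, dup$values[2, ])
  dup$feature_names <- c(pr$features$feature_names, "dup")
  sel <- gram_schmidt_select(dup, pr$kinematics, k = 5)
  picks <- sel$selected_indices
  expect_false(all(c(2, 6) %in% picks))
})

test_that("selection is invariant to positive feature rescaling", {
  pr <- make_pair(p = 8, seed = 61)
  sel1 <- gram_schmidt_select(pr$features, pr$kinematics, k = 4)
  scaled <- pr$features
  scaled$values <- diag(c(10, 0.1, 3, 7, 0.5, 2, 40, 1)) %*% scaled$values
  sel2 <- gram_schmidt_select(scaled, pr$kinematics, k = 4)
  expect_equal(sel1$selected_indices, sel2$selected_indices)
})

test_that("residuals of selected features are mutually orthogonal", {
  pr <- make_pair(p = 8, seed = 71)
  sel <- gram_schmidt_select(pr$features, pr$kinematics, k = 5)
  Fc <- scale(t(pr$features$values[sel$selected_indices, ]),
              scale = FALSE)
  # re-run Gram-Schmidt on the selected columns in order
  Q <- matrix(0, nrow(Fc), 0)
  for (j in seq_len(ncol(Fc))) {
    v <- Fc[, j]
    if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
    Q <- cbind(Q, v / sqrt(sum(v^2)))
  }
  G <- crossprod(Q)
  expect_equal(G, diag(ncol(Q)), tolerance = 1e-8)
})

test_that("selection stops early when residuals vanish, with a warning", {
  # 3 frames of 5 features: rank <= 2 after centering
  feats <- feature_series(matrix(rnorm(5 * 3), 5), 30)
  kin <- kinematic_trace(matrix(c(-0.5, 0, 0.5), 1), 30)
  expect_warning(sel <- gram_schmidt_select(feats, kin, k = 5),
                 "exhausted")
  expect_lt(length(sel$selected_indices), 5)
  expect_error(gram_schmidt_select(feats, kin, k = 0),
               class = "emgdec_config_error")
})
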