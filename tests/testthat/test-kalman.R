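# Kalman decoder: fitting, recursion, thresholds

linear_training_set <- function(n = 400, p = 6, d = 2, seed = 5,
                                noise = 0) {
  set.seed(seed)
  kin <- smooth_kinematics(n, d, seed)
  C0 <- matrix(runif(p * d, -2, 2), p, d)
  feats <- feature_series(C0 %*% kin$positions +
                            noise * matrix(rnorm(p * n), p), 30)
  list(train = training_set(feats, kin), C0 = C0)
}

test_that("least-squares fit recovers a noiseless observation matrix", {
  lt <- linear_training_set()
  model <- fit_kalman(lt$train)
  expect_equal(model$C, lt$C0, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(model$Q)), 1e-10)
})

test_that("state-transition fit recovers an exact AR(1) decay", {
  x <- matrix(0.9^(0:199), 1)  # exact x[t+1] = 0.9 x[t]
  kin <- kinematic_trace(x, 30)
  feats <- feature_series(rbind(x, -x) + 0.0, 30)
  model <- fit_kalman(training_set(feats, kin))
  expect_equal(model$A[1, 1], 0.9, tolerance = 1e-9)
  expect_lt(max(abs(model$W)), 1e-12)
  # multi-DOF seeded AR(1) with noise recovers A ~ 0.9 I
  set.seed(8)
  n <- 2000
  X <- matrix(0, 2, n)
  for (t in 2:n) X[, t] <- 0.9 * X[, t - 1] + rnorm(2, sd = 0.05)
  kin2 <- kinematic_trace(clamp(X), 30)
  feats2 <- feature_series(matrix(rnorm(3 * n), 3) + rbind(X, 0), 30)
  m2 <- fit_kalman(training_set(feats2, kin2))
  expect_equal(m2$A, 0.9 * diag(2), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("steady-state gain matches the scalar Riccati recursion", {
  a <- 0.9; w <- 0.04; cc <- 1.5; q <- 0.25
  model <- structure(
    list(A = matrix(a), W = matrix(w), C = matrix(cc), Q = matrix(q),
         thresholds = 0, dof_names = "d1", feature_names = "f1"),
    class = "kalman_model")
  # oracle: iterate the scalar Riccati recursion to convergence
  P <- 1
  for (i in 1:500) {
    Pp <- a^2 * P + w
    K <- Pp * cc / (cc^2 * Pp + q)
    P <- (1 - K * cc) * Pp
  }
  # run the filter; posterior variance and constant-input fixed point
  state <- kalman_init(model)
  z <- 0.6
  for (i in 1:500) {
    st <- kalman_step(model, state, z)
    state <- st$state
  }
  expect_equal(state$P[1, 1], P, tolerance = 1e-10)
  x_star <- K * z / (1 - (1 - K * cc) * a)
  expect_equal(state$x, x_star, tolerance = 1e-8)
})

test_that("zero features keep a stable filter at rest; outputs clamp", {
  lt <- linear_training_set(noise = 0.05)
  model <- fit_kalman(lt$train)
  state <- kalman_init(model)
  for (i in 1:50) {
    st <- kalman_step(model, state, rep(0, 6))
    state <- st$state
  }
  expect_lt(max(abs(state$x)), 1e-6)
  expect_true(all(abs(st$raw_estimate) <= 1))
  big <- predict_stream(model, feature_series(
    matrix(50, 6, 20), 30), raw = TRUE)
  expect_true(all(abs(big$positions) <= 1))
  expect_error(kalman_step(model, state, c(1, NA, 1, 1, 1, 1)),
               class = "emgdec_data_error")
})

test_that("covariance stays symmetric positive semidefinite under random input", {
  lt <- linear_training_set(noise = 0.1, seed = 9)
  model <- fit_kalman(lt$train)
  state <- kalman_init(model)
  set.seed(10)
  for (i in 1:2000) {
    st <- kalman_step(model, state, rnorm(6))
    state <- st$state
    if (i %% 200 == 0) {
      expect_equal(state$P, t(state$P), tolerance = 1e-12)
      expect_gte(min(eigen(state$P, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("dead-zone thresholding follows the rescaled contract", {
  expect_equal(apply_thresholds(c(-0.7, 0.2, 1), c(0, 0, 0)),
               c(-0.7, 0.2, 1))            # zero threshold = identity
  expect_equal(apply_thresholds(0.2, 0.3), 0)   # inside the dead zone
  expect_equal(apply_thresholds(1, 0.4), 1)     # full scale preserved
  expect_equal(apply_thresholds(-1, 0.4), -1)
  expect_equal(apply_thresholds(0.65, 0.3), (0.65 - 0.3) / 0.7)
  # continuity at the threshold edge and idempotence at zero
  eps <- 1e-9
  expect_lt(abs(apply_thresholds(0.3 + eps, 0.3) -
                  apply_thresholds(0.3 - eps, 0.3)), 1e-6)
  expect_equal(apply_thresholds(0, 0.3), 0)
  # monotone non-decreasing over a dense grid
  v <- seq(-1, 1, by = 1e-3)
  out <- apply_thresholds(v, 0.25)
  expect_true(all(diff(out) >= -1e-12))
  expect_error(apply_thresholds(0.5, 1.2), class = "emgdec_config_error")
})

test_that("threshold optimization prefers zero on clean data, >0 on noisy rest", {
  lt <- linear_training_set(noise = 0)
  model <- fit_kalman(lt$train)
  model0 <- optimize_thresholds(model, lt$train)
  expect_true(all(model0$thresholds <= 0.02))
  # grid {0} forces zero
  g0 <- optimize_thresholds(model, lt$train, grid = 0)
  expect_equal(as.vector(g0$thresholds), c(0, 0))
  expect_error(optimize_thresholds(model, lt$train, grid = numeric()),
               class = "emgdec_config_error")
  # rest-period feature noise: a dead zone must not increase training MSE
  set.seed(12)
  n <- 600
  kin <- kinematic_trace(matrix(0, 2, n), 30)   # pure rest
  kin$positions[1, 100:200] <- 0.9              # one movement bout
  feats <- feature_series(lt$C0 %*% kin$positions +
                            0.4 * matrix(rnorm(6 * n), 6), 30)
  ts <- training_set(feats, kin)
  # the rest-dominated kinematics are rank-deficient: the documented
  # ridge fallback fires (once for A, once for C)
  warns <- capture_warnings(m <- fit_kalman(ts))
  expect_match(warns, "ridge", all = TRUE)
  m <- optimize_thresholds(m, ts)
  mse <- m$threshold_search$mse
  chosen <- match(m$thresholds, m$threshold_search$grid)
  for (i in 1:2)
    expect_lte(mse[i, chosen[i]], mse[i, 1])
  expect_gt(max(m$thresholds), 0)
})

test_that("kalman model JSON round-trip reproduces predictions", {
  lt <- linear_training_set(noise = 0.02)
  model <- optimize_thresholds(fit_kalman(lt$train), lt$train)
  f <- withr::local_tempfile(fileext = ".json")
  write_kalman_json(model, f)
  back <- read_kalman_json(f)
  feats <- lt$train$features
  expect_equal(predict_stream(back, feats)$positions,
               predict_stream(model, feats)$positions,
               tolerance = 1e-12)
})
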