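# Preprocessing and MAV feature extraction

sine <- function(freq, rate = 1000, dur_s = 4) {
  sin(2 * pi * freq * seq(0, dur_s, by = 1 / rate))
}

steady_amplitude <- function(x) {
  tail_x <- x[(length(x) - 999):length(x)]  # last second, transient gone
  (max(tail_x) - min(tail_x)) / 2
}

test_that("high-pass stage rejects DC", {
  raw <- raw_emg(matrix(100, 1, 4000), 1000)
  out <- preprocess(raw)
  expect_lt(max(abs(out$samples[1, 3000:4000])), 1)
})

test_that("measured sine attenuation matches the cascade transfer function", {
  spec <- filter_spec()
  for (freq in c(60, 100, 500)) {
    raw <- raw_emg(matrix(sine(freq), 1), 1000)
    measured <- steady_amplitude(preprocess(raw, spec)$samples[1, ])
    expected <- filter_response(spec, freq, 1000)
    expect_equal(measured, expected, tolerance = 0.02,
                 label = sprintf("gain at %g Hz", freq))
  }
  # the notch cuts 60 Hz far below a neighbouring passband frequency
  g <- filter_response(spec, c(60, 100), 1000)
  expect_lt(g[1] / g[2], 0.05)
  # 500 Hz sits beyond the 375 Hz 2nd-order low-pass corner
  expect_lt(filter_response(spec, 500, 1000), 0.5)
})

test_that("filtering is causal: the future does not change the past", {
  set.seed(1)
  x <- matrix(rnorm(2 * 2000), 2)
  full <- preprocess(raw_emg(x, 1000))
  cut <- preprocess(raw_emg(x[, 1:1200], 1000))
  expect_equal(full$samples[, 1:1200], cut$samples)
})

test_that("preprocess validates rate and finiteness and drops bad channels", {
  x <- matrix(rnorm(3 * 1000), 3)
  expect_error(preprocess(raw_emg(x, 600)), class = "emgdec_config_error")
  xb <- x; xb[2, 5] <- NA
  expect_error(preprocess(raw_emg(xb, 1000)), class = "emgdec_data_error")
  out <- preprocess(raw_emg(x, 1000, c("a", "b", "c"), bad_channels = "b"))
  expect_equal(out$channel_ids, c("a", "c"))
})

test_that("differential expansion yields n + n(n-1)/2 ordered channels", {
  for (n in 2:32) {
    raw <- raw_emg(matrix(seq_len(n * 3), n, 3), 1000)
    out <- expand_differential(raw)
    expect_equal(nrow(out$samples), n + n * (n - 1) / 2)
  }
  # 32 monopolar channels give the standard 528 features
  raw32 <- expand_differential(raw_emg(matrix(0, 32, 3), 1000))
  expect_equal(nrow(raw32$samples), 528)
  # pair ordering and signs: (i, j), i < j, value = ch_i - ch_j
  r <- raw_emg(matrix(c(1, 10, 100), 3, 2), 1000, c("a", "b", "c"))
  out <- expand_differential(r)
  expect_equal(out$channel_ids, c("a", "b", "c", "a-b", "a-c", "b-c"))
  expect_equal(out$samples[, 1], c(1, 10, 100, -9, -99, -90),
               ignore_attr = TRUE)
  expect_error(expand_differential(raw_emg(matrix(0, 1, 3), 1000)),
               class = "emgdec_config_error")
})

test_that("MAV frames match a brute-force trailing-window mean", {
  set.seed(7)
  raw <- raw_emg(matrix(rnorm(3 * 1500), 3), 1000)
  fs <- mav_features(raw, buffer_ms = 300, frame_rate = 30)
  # independent double-loop oracle
  buf <- 300; hop <- 33
  ends <- seq(buf, 1500, by = hop)
  for (ch in 1:3) {
    for (k in seq_along(ends)) {
      expected <- mean(abs(raw$samples[ch, (ends[k] - buf + 1):ends[k]]))
      expect_equal(unname(fs$values[ch, k]), expected, tolerance = 1e-12)
    }
  }
  expect_equal(fs$frame_rate, 1000 / 33)
})

test_that("MAV of simple signals and degenerate inputs behave", {
  const <- raw_emg(matrix(-2, 1, 700), 1000)
  expect_true(all(mav_features(const)$values == 2))
  square <- raw_emg(matrix(rep(c(1, -1), 500), 1, 1000), 1000)
  expect_true(all(mav_features(square)$values == 1))
  expect_error(mav_features(raw_emg(matrix(0, 1, 100), 1000)),
               class = "emgdec_data_error")
})

test_that("MAV frames are causal in the raw stream", {
  set.seed(2)
  x <- matrix(rnorm(2 * 1200), 2)
  full <- mav_features(raw_emg(x, 1000))
  cut <- mav_features(raw_emg(x[, 1:900], 1000))
  n <- ncol(cut$values)
  expect_equal(full$values[, 1:n], cut$values)
})

test_that("baseline estimation and floored subtraction", {
  set.seed(3)
  vals <- matrix(abs(rnorm(4 * 400, mean = 5)), 4)
  fs <- feature_series(vals, frame_rate = 30)
  bl <- estimate_baseline(fs, window_s = 10)
  idx <- (ncol(vals) - ceiling(10 * 30) + 1):ncol(vals)
  expect_equal(bl$mean_activity, rowMeans(vals[, idx]),
               ignore_attr = TRUE)
  # constant features give their own value; zero gives zero
  cs <- feature_series(matrix(7, 2, 400), 30)
  expect_equal(estimate_baseline(cs)$mean_activity, c(7, 7),
               ignore_attr = TRUE)
  # subtraction floors at zero and is the identity for a zero baseline
  out <- subtract_baseline(fs, bl)
  expect_true(all(out$values >= 0))
  zero_bl <- structure(list(mean_activity = rep(0, 4), duration_s = 10),
                       class = "baseline_profile")
  expect_equal(subtract_baseline(fs, zero_bl)$values, fs$values)
  small <- feature_series(matrix(3, 1, 5), 30)
  big_bl <- structure(list(mean_activity = 5, duration_s = 10),
                      class = "baseline_profile")
  expect_true(all(subtract_baseline(small, big_bl)$values == 0))
  expect_error(estimate_baseline(feature_series(matrix(1, 1, 5), 30)),
               class = "emgdec_data_error")
  expect_error(subtract_baseline(fs, big_bl),
               class = "emgdec_config_error")
})

test_that("raw EMG and feature CSV round-trips preserve the data", {
  set.seed(4)
  raw <- raw_emg(matrix(rnorm(3 * 50), 3), 1000,
                 channel_ids = c("a", "b", "c"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_raw_emg_csv(raw, f1)
  back <- read_raw_emg_csv(f1)
  expect_equal(back$samples, raw$samples, tolerance = 1e-9)
  expect_equal(back$rate, 1000, tolerance = 1e-6)
  fs <- mav_features(raw_emg(matrix(rnorm(2 * 800), 2), 1000))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fs, f2)
  fs2 <- read_feature_csv(f2)
  expect_equal(fs2$values, fs$values, tolerance = 1e-9)
})
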