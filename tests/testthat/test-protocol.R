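# Mimicry-training protocol generation and merging

test_that("individual trials have protocol durations and trapezoid shape", {
  fr <- 30
  t44 <- gen_individual_trial(movement_spec("hand", 1), fr)
  expect_equal(ncol(t44$positions) - 1, 4.4 * fr, tolerance = 1 / fr)
  t66 <- gen_individual_trial(
    movement_spec("hand", 1, rise_s = 0.7, hold_s = 5.2, fall_s = 0.7), fr)
  expect_equal((ncol(t66$positions) - 1) / fr, 6.6, tolerance = 1 / fr)
  # plateau at full amplitude, linear rise
  tt <- seq(0, 4.4, by = 1 / fr)
  expect_equal(t44$positions["hand", tt >= 0.7 & tt < 3.7],
               rep(1, sum(tt >= 0.7 & tt < 3.7)), ignore_attr = TRUE)
  expect_equal(unname(t44$positions["hand", 2]), (1 / fr) / 0.7,
               tolerance = 1e-9)
  # hold = 0 gives a triangle peaking at t = rise
  tri <- gen_individual_trial(movement_spec("w", 1, hold_s = 0,
                                            rise_s = 0.5, fall_s = 0.5),
                              frame_rate = 10)
  expect_equal(max(tri$positions), 1)
  expect_equal(which.max(tri$positions), 6)  # t = 0.5 at 10 Hz
})

test_that("combination trials nest the secondary inside the primary plateau", {
  fr <- 100  # fine grid to check the printed timing exactly
  spec <- combination_spec(
    movement_spec("hand", 1, rise_s = 0.7, hold_s = 5.2, fall_s = 0.7),
    movement_spec("wrist", -1))
  tr <- gen_combination_trial(spec, fr)
  tt <- (seq_len(ncol(tr$positions)) - 1) / fr
  expect_equal(max(tt), 6.6, tolerance = 1 / fr)
  # secondary onset 1.1 s after trial start (0.7 rise + 0.4 delay)
  moving <- which(abs(tr$positions["wrist", ]) > 1e-12)
  expect_equal(tt[moving[1]], 1.1, tolerance = 1.5 / fr)
  # both DOFs at plateau on [1.8, 4.8]
  mid <- tt >= 1.8 & tt <= 4.8
  expect_true(all(tr$positions["hand", mid] == 1))
  expect_true(all(tr$positions["wrist", mid] == -1))
  # a secondary outlasting the primary plateau is rejected
  expect_error(
    combination_spec(movement_spec("hand", 1),
                     movement_spec("wrist", 1, hold_s = 5)),
    class = "emgdec_config_error")
})

test_that("phase-one schedule has the protocol period composition", {
  sch <- build_phase1_schedule()
  counts <- schedule_trial_counts(sch)
  expect_equal(as.vector(counts), c(48, 16, 32))
  p3 <- Filter(function(tr) tr$period == "period3", sch$trials)
  expect_equal(length(unique(vapply(p3, function(tr) tr$move$label,
                                    character(1)))), 8)
  expect_true(all(vapply(p3, function(tr)
    inherits(tr$move, "combination_spec"), logical(1))))
})

test_that("phase-two schedule has 20 individual and 36 trials per grip period", {
  sch <- build_phase2_schedule()
  counts <- schedule_trial_counts(sch)
  expect_equal(as.vector(counts), c(20, 36, 36, 36))
  p2 <- Filter(function(tr) tr$period == "period2", sch$trials)
  labels <- unique(vapply(p2, function(tr) tr$move$label, character(1)))
  expect_equal(length(labels), 9)  # grip alone + 4 + 4 reversed
})

test_that("rendered schedules rest at the ends and stay bounded", {
  sch <- mini_schedule(1)
  kin <- gen_schedule_kinematics(sch, frame_rate = 30, rest_gap_s = 2)
  expect_true(all(abs(kin$positions) <= 1))
  expect_equal(kin$positions[, 1], c(hand = 0, wrist = 0))
  expect_equal(kin$positions[, ncol(kin$positions)],
               c(hand = 0, wrist = 0))
  expect_equal(length(kin$trial_boundaries), 4)
  # every combination trial includes a nonempty two-DOF plateau
  sch1 <- build_phase1_schedule()
  combo <- Filter(function(tr) inherits(tr$move, "combination_spec"),
                  sch1$trials)[[1]]
  tr <- gen_combination_trial(combo$move, 30, sch1$dof_names)
  both <- colSums(abs(tr$positions) == 1) == 2
  expect_gt(sum(both), 0)
})

test_that("trial order permutes only under an explicit seed", {
  a <- build_phase1_schedule()
  b <- build_phase1_schedule()
  expect_identical(vapply(a$trials, function(tr) tr$move$label,
                          character(1)),
                   vapply(b$trials, function(tr) tr$move$label,
                          character(1)))
  s1 <- build_phase1_schedule(shuffle_seed = 5)
  s2 <- build_phase1_schedule(shuffle_seed = 5)
  expect_identical(vapply(s1$trials, function(tr) tr$move$label,
                          character(1)),
                   vapply(s2$trials, function(tr) tr$move$label,
                          character(1)))
  expect_false(identical(
    vapply(s1$trials, function(tr) tr$move$label, character(1)),
    vapply(a$trials, function(tr) tr$move$label, character(1))))
  # periods keep their protocol order even when shuffled
  expect_identical(unique(vapply(s1$trials, function(tr) tr$period,
                                 character(1))),
                   c("period1", "period2", "period3"))
})

test_that("merging balances durations and preserves provenance", {
  ds <- mini_dataset(reps = 2)
  set_a <- ds$train
  # merging a set with itself doubles duration in the same feature space
  doubled <- merge_training_sets(set_a, set_a, equalize = FALSE)
  expect_equal(ncol(doubled$features$values),
               2 * ncol(set_a$features$values))
  expect_equal(nrow(doubled$features$values),
               nrow(set_a$features$values))
  expect_equal(emgdec:::n_trials(doubled), 2 * emgdec:::n_trials(set_a))
  # unequal durations are truncated at a trial boundary, with a warning
  long <- mini_dataset(reps = 3)$train
  expect_warning(m <- merge_training_sets(long, set_a), "truncating")
  expect_lt(abs(emgdec:::set_duration_s(m) / 2 -
                  emgdec:::set_duration_s(set_a)), 8)
  expect_error(
    merge_training_sets(set_a, mini_dataset(n_channels = 6)$train),
    class = "emgdec_config_error")
})

test_that("phase-one condition sets have equal trial durations by design", {
  sch <- build_phase1_schedule()
  dur <- function(periods) {
    trs <- Filter(function(tr) tr$period %in% periods, sch$trials)
    sum(vapply(trs, function(tr) emgdec:::trial_duration(tr$move),
               numeric(1)))
  }
  expect_equal(dur(c("period1", "period2")), dur(c("period2", "period3")))
  expect_equal(dur("period1"), 48 * 4.4)
  expect_equal(dur("period3"), 32 * 6.6)
})

test_that("schedules and traces serialize losslessly enough to reload", {
  sch <- mini_schedule(1)
  f <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(sch, f)
  obj <- jsonlite::read_json(f)
  expect_equal(length(obj$trials), 4)
  kin <- gen_schedule_kinematics(sch, frame_rate = 30)
  fk <- withr::local_tempfile(fileext = ".csv")
  write_kinematic_csv(kin, fk)
  back <- read_kinematic_csv(fk)
  expect_equal(back$positions, kin$positions, tolerance = 1e-9,
               ignore_attr = TRUE)
})
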