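#' Run configuration for a decoding condition
#'
#' One experimental condition of the decoder comparison: which protocol
#' phase, decoder algorithm, training composition and output smoothing
#' to use. Phase one crosses three algorithms, two training types and
#' two output types (12 conditions); phase two runs the three
#' algorithms with combination training and smoothing.
#'
#' @param phase 1 or 2.
#' @param decoder `"mkf"`, `"mlp"` or `"cnn"`.
#' @param training_type `"individual"` or `"combination"`.
#' @param latching apply the latching filter to the decoder output.
#' @param seed integer seed for simulation and training.
#' @param n_channels,snr_db synthetic-recording parameters (see
#'   [synth_config()]).
#' @param k_features number of Gram-Schmidt-selected features for the
#'   mKF and MLP (default 48).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phase = 1, decoder = c("mkf", "mlp", "cnn"),
                       training_type = c("combination", "individual"),
                       latching = TRUE, seed = 1, n_channels = 32,
                       snr_db = 20, k_features = 48) {
  if (!phase %in% c(1, 2)) abort_config("phase must be 1 or 2")
  decoder <- match.arg(decoder)
  training_type <- match.arg(training_type)
  structure(
    list(phase = phase, decoder = decoder, training_type = training_type,
         latching = isTRUE(latching), seed = as.integer(seed),
         n_channels = n_channels, snr_db = snr_db,
         k_features = k_features),
    class = "run_config")
}

#' Enumerate the experimental conditions of a phase
#'
#' Phase 1: the full factorial of three algorithms, two training
#' paradigms and two output types (12 decoders). Phase 2: the three
#' algorithms with combination training and latched output.
#'
#' @param phase 1 or 2.
#' @param seed seed copied into every configuration.
#' @return List of [run_config()]s.
#' @export
enumerate_conditions <- function(phase = 1, seed = 1) {
  if (!phase %in% c(1, 2)) abort_config("phase must be 1 or 2")
  if (phase == 1) {
    grid <- expand.grid(decoder = c("mkf", "mlp", "cnn"),
                        training_type = c("individual", "combination"),
                        latching = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i)
      run_config(1, grid$decoder[i], grid$training_type[i],
                 grid$latching[i], seed = seed))
  } else {
    lapply(c("mkf", "mlp", "cnn"), function(d)
      run_config(2, d, "combination", TRUE, seed = seed))
  }
}

condition_label <- function(cfg) {
  paste(cfg$decoder, cfg$training_type,
        if (cfg$latching) "latched" else "raw", sep = "_")
}

# period composition per phase / training type
training_periods <- function(phase, training_type) {
  if (phase == 1) {
    if (training_type == "individual") list(c("period1"), c("period2"))
    else list(c("period2"), c("period3"))
  } else {
    list(c("period1", "period2"), c("period3", "period4"))
  }
}

#' Train a decoder on a training set
#'
#' Shared training front-end: temporally aligns the set, restricts to
#' Gram-Schmidt-selected features for the mKF and MLP (the CNN uses all
#' features), and fits the requested decoder. The mKF additionally gets
#' its per-DOF output thresholds optimized on the training data.
#'
#' @param train a [training_set()] of full features.
#' @param decoder `"mkf"`, `"mlp"` or `"cnn"`.
#' @param seed training seed.
#' @param k features to select for mkf/mlp (default 48, capped at the
#'   available count).
#' @param align run [align_lag()] / [apply_alignment()] first.
#' @return `list(model, selection, alignment, report)`; the model keeps
#'   the selected indices so [decode_condition()] can restrict test
#'   streams identically.
#' @export
train_decoder <- function(train, decoder = c("mkf", "mlp", "cnn"),
                          seed = 1, k = 48, align = TRUE) {
  decoder <- match.arg(decoder)
  alignment <- NULL
  if (align) {
    alignment <- align_lag(train$features, train$kinematics)
    train <- apply_alignment(train, alignment$lag_frames)
  }
  selection <- NULL
  report <- NULL
  if (decoder %in% c("mkf", "mlp")) {
    k <- min(k, nrow(train$features$values))
    selection <- gram_schmidt_select(train$features, train$kinematics, k)
    train_sel <- select_features(train, selection)
    if (decoder == "mkf") {
      model <- fit_kalman(train_sel)
      model <- optimize_thresholds(model, train_sel)
    } else {
      fit <- fit_mlp(train_sel, seed = seed)
      model <- fit$model; report <- fit$report
    }
    model$selected_indices <- selection$selected_indices
  } else {
    fit <- fit_cnn(train, seed = seed)
    model <- fit$model; report <- fit$report
  }
  list(model = model, selection = selection, alignment = alignment,
       report = report)
}

#' Decode a feature stream under a condition
#'
#' Applies the model's feature selection (if any), runs
#' [predict_stream()], and optionally smooths with the latching filter.
#'
#' @param model a trained decoder from [train_decoder()].
#' @param features a full [feature_series()].
#' @param latching apply [latch_stream()].
#' @param latch a [latch_config()].
#' @return A decoded [kinematic_trace()].
#' @export
decode_condition <- function(model, features, latching = FALSE,
                             latch = latch_config()) {
  if (!is.null(model$selected_indices))
    features <- select_features(features, model$selected_indices)
  out <- predict_stream(model, features)
  if (latching) out <- latch_stream(out, latch)
  out
}

#' Run one end-to-end synthetic condition
#'
#' The full pipeline for one [run_config()]: simulate the phase's
#' mimicry protocol, extract features, merge the condition's training
#' periods, align/select/train the decoder, decode a held-out synthetic
#' session, optionally latch, and compute per-DOF accuracy (and, for
#' phase 1, the simultaneity proportion). When `out_dir` is given, the
#' decoded trace, model, metrics and a reproducibility manifest are
#' written there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @param schedule optional replacement training schedule (defaults to
#'   the phase's full protocol; tests and demos can pass a smaller one).
#' @param test_schedule optional held-out schedule (defaults to one
#'   trial of each individual movement).
#' @return A list: `metrics` (per-DOF correlation/RMSE, simultaneity for
#'   phase 1), `decoded`, `model`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, schedule = NULL,
                         test_schedule = NULL) {
  if (!inherits(config, "run_config")) abort_config("config required")
  schedule <- schedule %||%
    (if (config$phase == 1) build_phase1_schedule()
     else build_phase2_schedule())
  synth <- synth_config(n_dof = length(schedule$dof_names),
                        dof_names = schedule$dof_names,
                        n_channels = config$n_channels,
                        snr_db = config$snr_db, seed = config$seed)
  pergroup <- training_periods(config$phase, config$training_type)
  have <- unique(vapply(schedule$trials, function(tr) tr$period,
                        character(1)))
  pergroup <- lapply(pergroup, intersect, have)
  sets <- lapply(seq_along(pergroup), function(i) {
    if (!length(pergroup[[i]])) return(NULL)
    synth_i <- synth; synth_i$seed <- synth$seed + i
    make_training_set(schedule, synth_i, periods = pergroup[[i]])$train
  })
  sets <- Filter(Negate(is.null), sets)
  train <- Reduce(function(a, b) merge_training_sets(a, b,
                                                     equalize = FALSE),
                  sets)
  fit <- train_decoder(train, config$decoder, seed = config$seed,
                       k = config$k_features)
  # held-out session: one trial of each individual movement
  test_schedule <- test_schedule %||% holdout_schedule(schedule)
  synth_test <- synth; synth_test$seed <- synth$seed + 101L
  test <- make_training_set(test_schedule, synth_test)$train
  decoded <- decode_condition(fit$model, test$features,
                              latching = config$latching)
  truth <- test$kinematics$positions
  metrics <- list(
    condition = condition_label(config),
    per_dof_correlation = per_dof_correlation(decoded$positions, truth),
    rmse = sqrt(mean((decoded$positions - truth)^2)))
  if (config$phase == 1)
    metrics$simultaneity <-
      simultaneous_proportion(decoded)$proportion
  manifest <- list(config = unclass(config),
                   condition = condition_label(config),
                   n_train_frames = ncol(train$features$values),
                   n_features = nrow(train$features$values),
                   alignment_lag = fit$alignment$lag_frames)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_kinematic_csv(decoded, file.path(out_dir, "decoded.csv"))
    write_model_json(fit$model, file.path(out_dir, "model.json"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$checksums <- as.list(tools::md5sum(
      file.path(out_dir, c("decoded.csv", "model.json"))))
    names(manifest$checksums) <- c("decoded.csv", "model.json")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, decoded = decoded, model = fit$model,
       manifest = manifest)
}

# one trial of each individual movement found in the schedule
holdout_schedule <- function(schedule) {
  singles <- Filter(function(tr) inherits(tr$move, "movement_spec"),
                    schedule$trials)
  labels <- vapply(singles, function(tr) tr$move$label, character(1))
  singles <- singles[!duplicated(labels)]
  trials <- lapply(singles, function(tr)
    list(move = tr$move, rep = 1L, period = "holdout"))
  new_schedule(trials, schedule$dof_names, schedule$phase)
}

per_dof_correlation <- function(pred, truth) {
  stats::setNames(vapply(seq_len(nrow(truth)), function(i) {
    if (stats::sd(truth[i, ]) < 1e-12 || stats::sd(pred[i, ]) < 1e-12)
      return(NA_real_)
    stats::cor(pred[i, ], truth[i, ])
  }, numeric(1)), rownames(truth))
}

#' Serialize any decoder model to JSON
#'
#' Matrices are stored row-major with shape metadata; [read_model_json()]
#' restores an equivalent model object.
#'
#' @param model a `kalman_model`, `mlp_model` or `cnn_model`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "kalman_model")) return(write_kalman_json(model, path))
  type <- if (inherits(model, "mlp_model")) "mlp" else "cnn"
  obj <- unclass(model)
  obj$type <- type
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "kalman") return(read_kalman_json(path))
  cls <- paste0(obj$type, "_model")
  obj$params <- lapply(obj$params, function(p)
    if (is.matrix(p)) p else as.numeric(p))
  obj$type <- NULL
  structure(obj, class = cls)
}
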