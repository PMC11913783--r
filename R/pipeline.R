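#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: the synthetic session layout, the
#' spectral feature extractor, ADC emulation, teacher-data count, ANN
#' training settings and the stabilizer depth. One master seed
#' deterministically derives the per-stage seeds (training-session
#' generation, evaluation-session generation, weight initialization,
#' retraining arms), so a config plus a master seed fixes every number
#' the pipeline produces.
#'
#' @param specs list of [motion_class_spec()]; defaults to the 4-class
#'   rest/grip/open/pinch set.
#' @param train_blocks data frame `motion_id`, `duration_s` for the
#'   labeling session; default 1.5 s per class.
#' @param eval_blocks same for the held-out evaluation session; default
#'   two 1-s visits to each class.
#' @param spectral a [spectral_config()].
#' @param mains_amplitude 50-Hz interference amplitude (V).
#' @param quantize_bits ADC depth, or `NULL` to skip ADC emulation.
#' @param frames_per_class teacher frames collected per motion.
#' @param stabilizer_n ring-buffer depth `N`.
#' @param learning_rate,epochs,batch ANN training settings, see
#'   [train_ann()].
#' @param seed master RNG seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(specs = default_motion_specs(),
                            train_blocks = NULL, eval_blocks = NULL,
                            spectral = spectral_config(),
                            mains_amplitude = 0.05,
                            quantize_bits = 12L,
                            frames_per_class = 100L,
                            stabilizer_n = 15L,
                            learning_rate = 0.01, epochs = 500L,
                            batch = "full",
                            seed = 1L) {
  ids <- vapply(specs, function(s) s$motion_id, integer(1))
  if (is.null(train_blocks)) {
    train_blocks <- tibble::tibble(motion_id = ids, duration_s = 1.5)
  }
  if (is.null(eval_blocks)) {
    reps <- c(ids, rev(ids))
    eval_blocks <- tibble::tibble(motion_id = reps, duration_s = 1.0)
  }
  structure(
    list(
      specs = specs,
      train_blocks = tibble::as_tibble(train_blocks),
      eval_blocks = tibble::as_tibble(eval_blocks),
      spectral = spectral,
      mains_amplitude = mains_amplitude,
      quantize_bits = quantize_bits,
      frames_per_class = as.integer(frames_per_class),
      stabilizer_n = as.integer(stabilizer_n),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      batch = batch,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# one master seed -> reproducible stage seeds
stage_seeds <- function(master) {
  s <- withr::with_seed(master, sample.int(.Machine$integer.max - 1L, 5L))
  setNames(s, c("train_gen", "eval_gen", "ann_init",
                "retrain_gen", "retrain_init"))
}

#' Per-frame true labels for a feature stream
#'
#' Assigns each analysis frame the motion of the label segment that fully
#' contains its window `[i * hop, i * hop + n_fft)`. Frames straddling a
#' segment boundary get `NA`: a window mixing two motions has no single
#' true label and is excluded from scoring.
#'
#' @param features feature tibble from [extract_features()].
#' @param labels a [label_track()].
#' @param cfg the [spectral_config()] used for extraction.
#' @return the feature tibble with `motion_id` (integer, `NA` at
#'   boundaries) and `segment` (segment row index) columns appended.
#' @export
frame_labels <- function(features, labels, cfg = spectral_config()) {
  starts <- features$frame_index * cfg$hop
  ends <- starts + cfg$n_fft
  seg <- rep(NA_integer_, nrow(features))
  mid <- rep(NA_integer_, nrow(features))
  for (j in seq_len(nrow(labels))) {
    inside <- starts >= labels$start_sample[j] & ends <= labels$end_sample[j]
    seg[inside] <- j
    mid[inside] <- labels$motion_id[j]
  }
  dplyr::mutate(features, motion_id = mid, segment = seg)
}

# simulate -> condition -> features -> per-frame labels, one session
session_features <- function(cfg, blocks, seed, shift = NULL) {
  script <- session_script(blocks,
    mains_amplitude = cfg$mains_amplitude,
    shift = shift, seed = seed
  )
  ses <- generate_session(cfg$specs, script,
                          sampling_rate = cfg$spectral$sampling_rate)
  rec <- ses$recording
  if (!is.null(cfg$quantize_bits)) rec <- quantize_adc(rec, cfg$quantize_bits)
  if (!is.null(cfg$spectral$softfilter_hz)) {
    rec <- software_highpass(rec, cfg$spectral$softfilter_hz)
  }
  feats <- extract_features(rec, cfg$spectral)
  frame_labels(feats, ses$labels, cfg$spectral)
}

# labeled session features -> teacher table (first frames_per_class
# in-segment frames per class, in label order)
collect_teacher <- function(labeled, frames_per_class) {
  classes <- sort(unique(labeled$motion_id[!is.na(labeled$motion_id)]))
  purrr::map_dfr(classes, function(cl) {
    stream <- dplyr::filter(labeled, .data$motion_id == cl)
    label_teacher_data(dplyr::select(stream, -"motion_id", -"segment"),
                       cl, frames_per_class)
  })
}

#' Score a prediction stream
#'
#' @param truth integer vector of true motion ids.
#' @param predicted integer vector of predicted motion ids, same length.
#' @return an `emg_eval` report: confusion matrix (rows = true, columns =
#'   predicted), overall recognition rate (`trace / total`), per-class
#'   rates and the scored-frame count.
#' @export
evaluate_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  classes <- sort(unique(c(truth, predicted)))
  f <- factor(truth, levels = classes)
  p <- factor(predicted, levels = classes)
  cm <- table(true = f, predicted = p)
  rate <- sum(diag(cm)) / max(1, sum(cm))
  per_class <- tibble::tibble(
    motion_id = as.integer(classes),
    n_frames = as.integer(rowSums(cm)),
    rate = ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
  )
  structure(
    list(
      confusion_matrix = unclass(cm),
      recognition_rate = rate,
      per_class_rate = per_class,
      n_frames = length(truth)
    ),
    class = "emg_eval"
  )
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("<emg_eval: %d frames, recognition rate %.3f", x$n_frames,
              x$recognition_rate))
  if (!is.null(x$pre_stabilizer_rate)) {
    cat(sprintf(" (pre-stabilizer %.3f)", x$pre_stabilizer_rate))
  }
  cat(">\n")
  print(x$confusion_matrix)
  invisible(x)
}

#' @export
tidy.emg_eval <- function(x, ...) {
  cm <- x$confusion_matrix
  tibble::tibble(
    true = rep(as.integer(rownames(cm)), times = ncol(cm)),
    predicted = rep(as.integer(colnames(cm)), each = nrow(cm)),
    n = as.vector(cm)
  )
}

#' @export
glance.emg_eval <- function(x, ...) {
  tibble::tibble(
    n_frames = x$n_frames,
    recognition_rate = x$recognition_rate,
    pre_stabilizer_rate = x$pre_stabilizer_rate %||% NA_real_,
    post_stabilizer_rate = x$post_stabilizer_rate %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classify every scored frame of a labeled evaluation stream, resetting
# the stabilizer at each label-segment boundary
classify_stream <- function(fit, labeled, stabilizer_n) {
  scored <- dplyr::filter(labeled, !is.na(.data$motion_id))
  raw <- predict(fit, scored)$.pred
  # segments are visited in order, so split() preserves the stream order
  voted <- unlist(lapply(split(raw, scored$segment), stabilize,
                         capacity = stabilizer_n),
                  use.names = FALSE)
  tibble::tibble(truth = scored$motion_id, raw = raw, voted = voted)
}

#' Run the full simulate-label-train-classify-evaluate pipeline
#'
#' Generates a labeling session and a disjoint evaluation session from
#' seeds derived from the master seed, collects teacher data, trains the
#' classifier, streams the evaluation frames through prediction and the
#' recognition-stabilization filter (reset at segment boundaries), and
#' scores both the raw and the stabilized stream. Frames whose analysis
#' window straddles a label boundary are excluded from scoring.
#'
#' @param cfg a [pipeline_config()].
#' @return an `emg_eval` report for the stabilized stream, with
#'   `pre_stabilizer_rate`, `post_stabilizer_rate` and the fitted model in
#'   `$fit`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' glance(rep)
#' }
#' @export
run_pipeline <- function(cfg) {
  seeds <- stage_seeds(cfg$seed)
  train_lab <- session_features(cfg, cfg$train_blocks, seeds[["train_gen"]])
  teacher <- collect_teacher(train_lab, cfg$frames_per_class)
  fit <- train_ann(teacher,
    learning_rate = cfg$learning_rate, epochs = cfg$epochs,
    batch = cfg$batch, seed = seeds[["ann_init"]]
  )
  eval_lab <- session_features(cfg, cfg$eval_blocks, seeds[["eval_gen"]])
  streams <- classify_stream(fit, eval_lab, cfg$stabilizer_n)
  report <- evaluate_predictions(streams$truth, streams$voted)
  report$pre_stabilizer_rate <- mean(streams$raw == streams$truth)
  report$post_stabilizer_rate <- report$recognition_rate
  report$fit <- fit
  report
}

#' Electrode-shift degradation and relearning experiment
#'
#' Reproduces, on synthetic sessions, the covariate-drift phenomenon that
#' forces prosthetic users to relearn after reattaching the socket: a
#' model trained before an electrode shift is evaluated on post-shift
#' data (degradation arm), and optionally a new model is trained on
#' post-shift teacher data and evaluated on the same shifted session
#' (recovery arm).
#'
#' @param cfg a [pipeline_config()].
#' @param shift a [shift_perturbation()] applied to the evaluation (and
#'   retraining) sessions.
#' @param retrain collect post-shift teacher data and retrain?
#' @return a list with `emg_eval` reports `baseline` (no shift),
#'   `degraded` (frozen model, shifted data) and `retrained` (`NULL`
#'   unless `retrain`).
#' @export
relearning_experiment <- function(cfg, shift, retrain = TRUE) {
  seeds <- stage_seeds(cfg$seed)
  train_lab <- session_features(cfg, cfg$train_blocks, seeds[["train_gen"]])
  teacher <- collect_teacher(train_lab, cfg$frames_per_class)
  fit <- train_ann(teacher,
    learning_rate = cfg$learning_rate, epochs = cfg$epochs,
    batch = cfg$batch, seed = seeds[["ann_init"]]
  )

  score <- function(model, labeled) {
    s <- classify_stream(model, labeled, cfg$stabilizer_n)
    rep <- evaluate_predictions(s$truth, s$voted)
    rep$pre_stabilizer_rate <- mean(s$raw == s$truth)
    rep$post_stabilizer_rate <- rep$recognition_rate
    rep
  }

  eval_clean <- session_features(cfg, cfg$eval_blocks, seeds[["eval_gen"]])
  eval_shift <- session_features(cfg, cfg$eval_blocks, seeds[["eval_gen"]],
                                 shift = shift)
  out <- list(
    baseline = score(fit, eval_clean),
    degraded = score(fit, eval_shift),
    retrained = NULL
  )
  if (retrain) {
    re_lab <- session_features(cfg, cfg$train_blocks,
                               seeds[["retrain_gen"]], shift = shift)
    re_teacher <- collect_teacher(re_lab, cfg$frames_per_class)
    re_fit <- train_ann(re_teacher,
      learning_rate = cfg$learning_rate, epochs = cfg$epochs,
      batch = cfg$batch, seed = seeds[["retrain_init"]]
    )
    out$retrained <- score(re_fit, eval_shift)
  }
  out
}

#' Serialize an evaluation report to JSON
#'
#' A fixed-layout JSON rendering of an `emg_eval` used for reproducibility
#' checks and the command-line interface: identical configs and master
#' seeds yield byte-identical strings.
#'
#' @param report an `emg_eval`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  cm <- report$confusion_matrix
  x <- list(
    n_frames = report$n_frames,
    recognition_rate = report$recognition_rate,
    pre_stabilizer_rate = report$pre_stabilizer_rate,
    post_stabilizer_rate = report$post_stabilizer_rate,
    classes = as.integer(rownames(cm)),
    confusion_matrix = unname(apply(cm, 1, as.integer, simplify = FALSE)),
    per_class_rate = report$per_class_rate
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
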