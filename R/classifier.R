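#' Label a feature stream as teacher data
#'
#' Pairs the first `frames_per_class` frames of a feature stream with a
#' motion id, emulating the labeling step in which the user performs a
#' motion while holding its button: frames are buffered until the target
#' count is reached, then collection stops.
#'
#' @param features a feature tibble from [extract_features()] (any extra
#'   columns are kept).
#' @param motion_id the intended motion's integer id.
#' @param frames_per_class number of frames to collect.
#' @return a tibble of `frames_per_class` rows with a `motion_id` column
#'   appended.
#' @export
label_teacher_data <- function(features, motion_id, frames_per_class = 100L) {
  if (nrow(features) < frames_per_class) {
    abort(sprintf(
      "feature stream exhausted: %d frames collected, %d requested.",
      nrow(features), frames_per_class
    ))
  }
  dplyr::mutate(
    dplyr::slice_head(features, n = frames_per_class),
    motion_id = as.integer(motion_id)
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass on normalized inputs; returns hidden and output activations
ann_forward <- function(w, xn) {
  h <- sigmoid(xn %*% w$w1 + rep(w$b1, each = nrow(xn)))
  o <- sigmoid(h %*% w$w2 + rep(w$b2, each = nrow(xn)))
  list(h = h, o = o)
}

# sum-of-squared-error loss and its gradients over the trained output
# slots (classic backprop through sigmoid hidden and output layers)
ann_loss_grad <- function(w, xn, targets, k) {
  fw <- ann_forward(w, xn)
  ok <- fw$o[, seq_len(k), drop = FALSE]
  err <- ok - targets
  loss <- 0.5 * sum(err^2)
  d_out <- err * ok * (1 - ok)
  d_hid <- (d_out %*% t(w$w2[, seq_len(k), drop = FALSE])) * fw$h * (1 - fw$h)
  g_w2 <- matrix(0, nrow(w$w2), ncol(w$w2))
  g_w2[, seq_len(k)] <- t(fw$h) %*% d_out
  g_b2 <- numeric(length(w$b2))
  g_b2[seq_len(k)] <- colSums(d_out)
  list(
    loss = loss,
    w1 = t(xn) %*% d_hid, b1 = colSums(d_hid),
    w2 = g_w2, b2 = g_b2
  )
}

#' Train the motion-intention classifier
#'
#' Fits a multilayer perceptron (default 24 inputs, 32 hidden, 8 output
#' units, sigmoid activations at both layers) to labeled teacher data by
#' gradient descent on the sum-of-squared-error against one-hot targets.
#' Features are min-max normalized to `[0, 1]` using ranges computed from
#' the teacher set; the normalization is stored with the weights and
#' re-applied at prediction time. Motion classes are assigned to the first
#' `|Y|` output slots in ascending motion-id order; remaining slots are
#' neither trained nor consulted. Training is exactly reproducible under a
#' fixed seed.
#'
#' @param teacher tibble of teacher data: feature columns (named
#'   `ch<k>_...`) plus `motion_id`.
#' @param hidden hidden-layer width.
#' @param n_output output-layer width; the class count may not exceed it.
#' @param learning_rate gradient-descent step size.
#' @param epochs training epochs.
#' @param batch `"sample"` for per-sample (online) updates in fixed
#'   sample order, `"full"` for one full-batch update per epoch.
#' @param seed RNG seed for the uniform `[-0.5, 0.5]` weight
#'   initialization.
#' @return an object of class `emg_ann`: weights, class map,
#'   normalization, per-epoch loss trace and the training settings.
#' @examples
#' teacher <- tibble::tibble(
#'   ch1_a = c(rnorm(20, 0), rnorm(20, 3)),
#'   ch1_b = c(rnorm(20, 3), rnorm(20, 0)),
#'   motion_id = rep(1:2, each = 20)
#' )
#' fit <- train_ann(teacher, epochs = 200, seed = 1)
#' glance(fit)
#' @export
train_ann <- function(teacher, hidden = 32L, n_output = 8L,
                      learning_rate = 0.01, epochs = 500L,
                      batch = c("full", "sample"), seed = 1L) {
  batch <- match.arg(batch)
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (!"motion_id" %in% names(teacher)) {
    abort("`teacher` needs a motion_id column.")
  }
  x <- feature_matrix(teacher)
  if (ncol(x) == 0) {
    # fall back to "all numeric columns except motion_id"
    num <- setdiff(names(teacher)[vapply(teacher, is.numeric, logical(1))],
                   "motion_id")
    x <- as.matrix(teacher[num])
  }
  y <- as.integer(teacher$motion_id)
  class_map <- sort(unique(y))
  k <- length(class_map)
  if (k > n_output) {
    abort(sprintf(
      "%d classes exceed the %d output-layer neurons.", k, n_output
    ))
  }
  d <- ncol(x)

  offset <- apply(x, 2, min)
  scale <- apply(x, 2, max) - offset
  scale[scale == 0] <- 1
  xn <- sweep(sweep(x, 2, offset), 2, scale, "/")
  targets <- matrix(0, nrow(x), k)
  targets[cbind(seq_len(nrow(x)), match(y, class_map))] <- 1

  w <- withr::with_seed(seed, list(
    w1 = matrix(runif(d * hidden, -0.5, 0.5), d, hidden),
    b1 = runif(hidden, -0.5, 0.5),
    w2 = matrix(runif(hidden * n_output, -0.5, 0.5), hidden, n_output),
    b2 = runif(n_output, -0.5, 0.5)
  ))

  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (batch == "full") {
      g <- ann_loss_grad(w, xn, targets, k)
      w$w1 <- w$w1 - learning_rate * g$w1
      w$b1 <- w$b1 - learning_rate * g$b1
      w$w2 <- w$w2 - learning_rate * g$w2
      w$b2 <- w$b2 - learning_rate * g$b2
      loss_trace[ep] <- g$loss
    } else {
      for (i in seq_len(nrow(xn))) {
        g <- ann_loss_grad(w, xn[i, , drop = FALSE],
                           targets[i, , drop = FALSE], k)
        w$w1 <- w$w1 - learning_rate * g$w1
        w$b1 <- w$b1 - learning_rate * g$b1
        w$w2 <- w$w2 - learning_rate * g$w2
        w$b2 <- w$b2 - learning_rate * g$b2
      }
      loss_trace[ep] <- ann_loss_grad(w, xn, targets, k)$loss
    }
  }

  structure(
    list(
      weights = w,
      class_map = class_map,
      normalization = list(offset = offset, scale = scale),
      feature_names = colnames(x),
      hidden = as.integer(hidden), n_output = as.integer(n_output),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch = batch, seed = as.integer(seed),
      n_samples = nrow(x),
      loss_trace = loss_trace
    ),
    class = "emg_ann"
  )
}

#' Predict motion intentions from features
#'
#' Runs the forward pass and picks the class whose assigned output unit
#' scores highest; ties break toward the smallest motion id.
#'
#' @param object an `emg_ann` from [train_ann()].
#' @param newdata a feature tibble (from [extract_features()]) or a
#'   numeric matrix with one row per frame.
#' @param ... unused.
#' @return a tibble with `.pred` (motion id) and one `score_<id>` column
#'   per learned class.
#' @export
predict.emg_ann <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(x) != length(object$normalization$offset)) {
    abort(sprintf(
      "feature length %d does not match the trained input layer (%d).",
      ncol(x), length(object$normalization$offset)
    ))
  }
  xn <- sweep(sweep(x, 2, object$normalization$offset), 2,
              object$normalization$scale, "/")
  k <- length(object$class_map)
  o <- ann_forward(object$weights, xn)$o[, seq_len(k), drop = FALSE]
  # max.col(ties.method = "first") + ascending class_map = smallest-id tie rule
  pred <- object$class_map[max.col(o, ties.method = "first")]
  scores <- tibble::as_tibble(o, .name_repair = "minimal")
  names(scores) <- paste0("score_", object$class_map)
  dplyr::bind_cols(tibble::tibble(.pred = pred), scores)
}

#' @export
print.emg_ann <- function(x, ...) {
  cat(sprintf(
    "<emg_ann: %d-%d-%d sigmoid MLP, %d classes (%s), %d epochs %s, final SSE %.4g>\n",
    length(x$normalization$offset), x$hidden, x$n_output,
    length(x$class_map), paste(x$class_map, collapse = ","),
    x$epochs, x$batch, tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' Tidy the fitted classifier's weights
#'
#' @param x an `emg_ann`.
#' @param ... unused.
#' @return a tibble with one row per weight: `layer` (`"hidden"` /
#'   `"output"`), `from`, `to` and `weight` (`from = "bias"` for bias
#'   terms).
#' @export
tidy.emg_ann <- function(x, ...) {
  w <- x$weights
  layer_tbl <- function(mat, bias, layer, from_names, to_names) {
    dplyr::bind_rows(
      tibble::tibble(
        layer = layer,
        from = rep(from_names, times = ncol(mat)),
        to = rep(to_names, each = nrow(mat)),
        weight = as.vector(mat)
      ),
      tibble::tibble(layer = layer, from = "bias", to = to_names,
                     weight = bias)
    )
  }
  dplyr::bind_rows(
    layer_tbl(w$w1, w$b1, "hidden", x$feature_names,
              paste0("h", seq_len(x$hidden))),
    layer_tbl(w$w2, w$b2, "output", paste0("h", seq_len(x$hidden)),
              paste0("out", seq_len(x$n_output)))
  )
}

#' One-row summary of a fitted classifier
#'
#' @param x an `emg_ann`.
#' @param ... unused.
#' @return a tibble with the architecture, sample count, epoch count and
#'   the initial / final sum-of-squared-error loss.
#' @export
glance.emg_ann <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_classes = length(x$class_map),
    n_features = length(x$normalization$offset),
    hidden = x$hidden,
    epochs = x$epochs,
    batch = x$batch,
    initial_loss = x$loss_trace[1],
    final_loss = tail(x$loss_trace, 1)
  )
}

#' Serialize / restore classifier parameters
#'
#' Writes the trained weights, class map and normalization to JSON (the
#' on-controller analogue is an EEPROM image). `load_params()` validates
#' shapes and reproduces bit-identical predictions.
#'
#' @param params an `emg_ann`.
#' @param path JSON file path.
#' @return `load_params()` returns the restored `emg_ann`;
#'   `save_params()` invisibly returns `path`.
#' @export
save_params <- function(params, path) {
  if (!inherits(params, "emg_ann")) abort("`params` must be an emg_ann.")
  jsonlite::write_json(
    list(
      format = "emgpr-ann-1",
      weights = lapply(params$weights, unclass),
      class_map = params$class_map,
      normalization = params$normalization,
      feature_names = params$feature_names,
      hidden = params$hidden, n_output = params$n_output,
      learning_rate = params$learning_rate, epochs = params$epochs,
      batch = params$batch, seed = params$seed,
      n_samples = params$n_samples,
      loss_trace = params$loss_trace
    ),
    path,
    # 17 significant digits: doubles survive the round trip bit-exactly
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) abort(paste0(
                  "cannot parse model file: ", conditionMessage(e)
                )))
  need <- c("weights", "class_map", "normalization", "hidden", "n_output")
  if (!all(need %in% names(p))) {
    abort("model file is missing required fields.")
  }
  w <- list(
    w1 = as.matrix(p$weights$w1), b1 = as.numeric(p$weights$b1),
    w2 = as.matrix(p$weights$w2), b2 = as.numeric(p$weights$b2)
  )
  d <- length(p$normalization$offset)
  if (!all(dim(w$w1) == c(d, p$hidden)) ||
      !all(dim(w$w2) == c(p$hidden, p$n_output)) ||
      length(w$b1) != p$hidden || length(w$b2) != p$n_output) {
    abort("model file weight shapes are inconsistent.")
  }
  cm <- as.integer(p$class_map)
  if (anyDuplicated(cm) || length(cm) > p$n_output) {
    abort("model file class_map is invalid.")
  }
  structure(
    list(
      weights = w, class_map = cm,
      normalization = list(
        offset = as.numeric(p$normalization$offset),
        scale = as.numeric(p$normalization$scale)
      ),
      feature_names = p$feature_names,
      hidden = as.integer(p$hidden), n_output = as.integer(p$n_output),
      learning_rate = p$learning_rate, epochs = as.integer(p$epochs),
      batch = p$batch, seed = as.integer(p$seed),
      n_samples = as.integer(p$n_samples),
      loss_trace = as.numeric(p$loss_trace)
    ),
    class = "emg_ann"
  )
}
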