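#' Recognition-stabilization filter: ring buffer with majority vote
#'
#' The classifier's per-frame prediction stream is smoothed by keeping the
#' last `N` predictions in a FIFO ring buffer and outputting the class
#' that occurs most often in it. Each step appends the newest prediction,
#' evicts the oldest once the buffer holds more than `N`, and takes the
#' argmax of per-class counts over the buffer. Ties break toward the
#' smallest motion id; during warm-up (fewer than `N` entries) the vote
#' runs over the entries present, so the filter emits an output every
#' frame from the first one.
#'
#' At the 10-ms frame period the default `capacity = 15` corresponds to a
#' ~150-ms smoothing horizon, a conventional latency budget for
#' myoelectric control.
#'
#' @param capacity `N`, the number of retained predictions.
#' @return `vote_buffer()` returns an empty buffer of class
#'   `vote_buffer`.
#' @examples
#' b <- vote_buffer(3)
#' step <- push_and_vote(b, 2)
#' step <- push_and_vote(step$buffer, 1)
#' step$output
#' @export
vote_buffer <- function(capacity = 15L) {
  if (capacity < 1) abort("`capacity` must be >= 1.")
  structure(list(capacity = as.integer(capacity), entries = integer(0)),
            class = "vote_buffer")
}

#' @rdname vote_buffer
#' @param buf a `vote_buffer`.
#' @param prediction the newest predicted motion id.
#' @return `push_and_vote()` returns a list with `output` (the voted
#'   motion id) and `buffer` (the updated buffer).
#' @export
push_and_vote <- function(buf, prediction) {
  if (!inherits(buf, "vote_buffer")) abort("`buf` must be a vote_buffer.")
  prediction <- as.integer(prediction)
  if (length(prediction) != 1 || is.na(prediction)) {
    abort("`prediction` must be a single motion id.")
  }
  entries <- c(buf$entries, prediction)
  if (length(entries) > buf$capacity) entries <- entries[-1]
  counts <- table(entries)
  # names(counts) sorts ascending, so which.max's first-hit rule breaks
  # ties toward the smallest motion id
  output <- as.integer(names(counts)[which.max(counts)])
  buf$entries <- entries
  list(output = output, buffer = buf)
}

#' @rdname vote_buffer
#' @export
reset_buffer <- function(buf) {
  if (!inherits(buf, "vote_buffer")) abort("`buf` must be a vote_buffer.")
  buf$entries <- integer(0)
  buf
}

#' @export
print.vote_buffer <- function(x, ...) {
  cat(sprintf("<vote_buffer: N=%d, holding %d (%s)>\n",
              x$capacity, length(x$entries),
              paste(x$entries, collapse = " ")))
  invisible(x)
}

#' Stabilize a whole prediction stream
#'
#' Streams a vector of per-frame predictions through the
#' recognition-stabilization filter starting from an empty buffer;
#' equivalent to repeated [push_and_vote()] but computed with O(1)
#' sliding-window count updates per step.
#'
#' @param predictions integer vector of per-frame motion ids.
#' @param capacity ring-buffer size `N`.
#' @return integer vector of voted outputs, same length as the input.
#' @export
stabilize <- function(predictions, capacity = 15L) {
  if (capacity < 1) abort("`capacity` must be >= 1.")
  n <- length(predictions)
  if (n == 0) return(integer(0))
  preds <- as.integer(predictions)
  classes <- sort(unique(preds))
  idx <- match(preds, classes)
  counts <- integer(length(classes))
  out <- integer(n)
  for (t in seq_len(n)) {
    counts[idx[t]] <- counts[idx[t]] + 1L
    if (t > capacity) {
      old <- idx[t - capacity]
      counts[old] <- counts[old] - 1L
    }
    out[t] <- classes[which.max(counts)]
  }
  out
}
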