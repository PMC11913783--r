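#' EMG recordings as channel-per-column tibbles
#'
#' An `emg_recording` is a tibble with one column per channel (`ch1`,
#' `ch2`, ...) holding voltages in volts, one row per sample, plus
#' attributes: `sampling_rate` (Hz), `t0` (start time, s) and `meta`
#' (free-form named list). Sample indexing throughout the package is
#' 0-based and label intervals are half-open `[start, end)`, so slicing a
#' recording by a segment yields exactly `end - start` rows.
#'
#' @param samples numeric matrix or data frame, one column per channel,
#'   voltages in volts.
#' @param sampling_rate sampling frequency in Hz (default 2000, the rate
#'   of the target acquisition hardware).
#' @param t0 start time in seconds.
#' @param meta named list of free-form annotations.
#' @return a tibble of class `emg_recording`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(600), ncol = 3))
#' n_channels(rec)
#' duration(rec)
#' @export
emg_recording <- function(samples, sampling_rate = 2000, t0 = 0,
                          meta = list()) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  storage.mode(samples) <- "double"
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (ncol(samples) < 1) abort("a recording needs at least one channel.")
  if (nrow(samples) > 0 && !all(is.finite(samples))) {
    abort("recording samples must be finite.")
  }
  colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  out <- tibble::as_tibble(samples)
  structure(out,
    class = c("emg_recording", class(out)),
    sampling_rate = sampling_rate, t0 = t0, meta = meta
  )
}

#' @rdname emg_recording
#' @param rec an `emg_recording`.
#' @export
sampling_rate <- function(rec) attr(rec, "sampling_rate")

#' @rdname emg_recording
#' @export
n_channels <- function(rec) ncol(rec)

#' @rdname emg_recording
#' @export
duration <- function(rec) nrow(rec) / sampling_rate(rec)

# plain double matrix view used by the numeric internals
rec_matrix <- function(rec) {
  m <- as.matrix(as.data.frame(rec))
  storage.mode(m) <- "double"
  m
}

# rebuild a recording around new sample values, keeping metadata
rec_update <- function(rec, samples, meta = attr(rec, "meta")) {
  emg_recording(samples,
    sampling_rate = sampling_rate(rec),
    t0 = attr(rec, "t0"), meta = meta
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording: %d samples x %d channels, %g Hz, %.3f s>\n",
    nrow(x), ncol(x), sampling_rate(x), duration(x)
  ))
  NextMethod()
}

#' Label tracks: motion annotations over sample intervals
#'
#' A `label_track` is a tibble with integer columns `start_sample`
#' (0-based, inclusive), `end_sample` (exclusive) and `motion_id`.
#' Segments must be sorted, non-overlapping and non-empty.
#'
#' @param segments a data frame with columns `start_sample`, `end_sample`,
#'   `motion_id`, or a list of `c(start, end, motion_id)` triples.
#' @return a tibble of class `label_track`.
#' @examples
#' label_track(data.frame(
#'   start_sample = c(0, 2000), end_sample = c(2000, 4000),
#'   motion_id = c(1, 2)
#' ))
#' @export
label_track <- function(segments) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, lapply(segments, function(s) {
      data.frame(start_sample = s[[1]], end_sample = s[[2]], motion_id = s[[3]])
    }))
  }
  need <- c("start_sample", "end_sample", "motion_id")
  if (!all(need %in% names(segments))) {
    abort(paste0(
      "label segments need columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  seg <- tibble::as_tibble(segments[need])
  seg <- dplyr::mutate(seg, dplyr::across(dplyr::everything(), as.integer))
  validate_label_track(seg)
  structure(seg, class = c("label_track", class(seg)))
}

validate_label_track <- function(seg) {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$start_sample < 0)) abort("label segments must start at >= 0.")
  if (any(seg$end_sample <= seg$start_sample)) {
    abort("label segments must satisfy end_sample > start_sample.")
  }
  if (is.unsorted(seg$start_sample, strictly = TRUE)) {
    abort("label segments must be sorted by start_sample.")
  }
  if (any(head(seg$end_sample, -1) > tail(seg$start_sample, -1))) {
    abort("label segments must not overlap.")
  }
  invisible(seg)
}

#' Slice a recording by one label segment
#'
#' @param rec an [emg_recording()].
#' @param segment one row of a [label_track()] (or anything with
#'   `start_sample` / `end_sample`).
#' @return the sub-recording covering `[start_sample, end_sample)`.
#' @export
slice_segment <- function(rec, segment) {
  i0 <- segment$start_sample[1]
  i1 <- segment$end_sample[1]
  if (i1 > nrow(rec)) abort("segment runs past the end of the recording.")
  rec_update(rec, rec_matrix(rec)[(i0 + 1):i1, , drop = FALSE])
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read / write EMG recordings as delimited text
#'
#' Recordings are stored as a CSV with a header row naming the channels
#' (`ch1..chC`) and a JSON sidecar (`<path>.json`) holding
#' `sampling_rate_hz`, `t0_s` and `meta`. If no sidecar is present,
#' `sampling_rate` must be supplied.
#'
#' @param path file path of the CSV.
#' @param sampling_rate sampling rate in Hz; overrides the sidecar when
#'   given.
#' @return `read_recording()` returns an [emg_recording()];
#'   `write_recording()` invisibly returns `path`.
#' @export
read_recording <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  side <- sidecar_path(path)
  t0 <- 0; meta <- list()
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(sampling_rate)) sampling_rate <- sc$sampling_rate_hz
    if (!is.null(sc$t0_s)) t0 <- sc$t0_s
    if (!is.null(sc$meta)) meta <- as.list(sc$meta)
  }
  if (is.null(sampling_rate)) {
    abort("no sidecar found; supply `sampling_rate` explicitly.")
  }
  df <- tryCatch(
    readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_double()),
      progress = FALSE
    ),
    error = function(e) abort(paste0("failed to parse ", path, ": ",
                                     conditionMessage(e)))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed recording %s: first problem at line %d (%s)",
      path, probs$row[1] + 1L, probs$expected[1]
    ))
  }
  if (nrow(df) == 0) abort(paste0("recording ", path, " holds no samples."))
  if (any(!vapply(df, is.numeric, logical(1)))) {
    abort("recording columns must all be numeric.")
  }
  emg_recording(df, sampling_rate = sampling_rate, t0 = t0, meta = meta)
}

#' @rdname read_recording
#' @param rec an [emg_recording()] to write.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(rec)), path,
                   progress = FALSE)
  jsonlite::write_json(
    list(
      sampling_rate_hz = sampling_rate(rec),
      t0_s = attr(rec, "t0"),
      meta = attr(rec, "meta")
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write label tracks
#'
#' Label tracks are CSVs with columns `start_sample`, `end_sample`,
#' `motion_id`; intervals are 0-based and half-open.
#'
#' @param path file path.
#' @return `read_labels()` returns a [label_track()]; `write_labels()`
#'   invisibly returns `path`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_integer()),
    progress = FALSE
  )
  label_track(df)
}

#' @rdname read_labels
#' @param track a [label_track()] to write.
#' @export
write_labels <- function(track, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(track)), path,
                   progress = FALSE)
  invisible(path)
}
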