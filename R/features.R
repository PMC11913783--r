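#' Spectral feature-extraction configuration
#'
#' Settings of the sliding-window FFT feature extractor: 256-sample Hann
#' frames with 236 samples of overlap (20-sample hop, i.e. a 10-ms frame
#' period at 2,000 Hz), 8 selected center frequencies per channel and
#' 5-point smoothing of the amplitude spectrum around each. Every selected
#' frequency must sit exactly on the FFT grid (a multiple of
#' `sampling_rate / n_fft` = 7.8125 Hz at the defaults); the defaults map
#' to bin indices 3, 6, 9, 12, 18, 24, 32 and 40.
#'
#' The default `softfilter_hz = 50` high-pass matches the acquisition
#' software. Note it sits above the two lowest selected frequencies
#' (23.4375 and 46.875 Hz), which it therefore attenuates; both stages are
#' kept exactly as configured and the high-pass can be disabled via
#' `softfilter_hz = NULL`. See the package vignette.
#'
#' @param n_fft frame length in samples.
#' @param overlap overlapping samples between consecutive frames.
#' @param window taper; only `"hann"` is supported.
#' @param selected_hz center frequencies (Hz) of the extracted features.
#' @param smoothing_points odd number of spectrum bins averaged around
#'   each selected bin.
#' @param sampling_rate Hz.
#' @param softfilter_hz software high-pass cutoff in Hz, or `NULL` to
#'   disable.
#' @return a `spectral_config` list with derived fields `hop`,
#'   `bin_width_hz` and `bins` (0-based bin indices).
#' @export
spectral_config <- function(n_fft = 256L, overlap = 236L, window = "hann",
                            selected_hz = c(23.4375, 46.875, 70.3125,
                                            93.75, 140.625, 187.5,
                                            250.0, 312.5),
                            smoothing_points = 5L, sampling_rate = 2000,
                            softfilter_hz = 50) {
  if (overlap >= n_fft) abort("`overlap` must be smaller than `n_fft`.")
  if (smoothing_points %% 2 != 1) abort("`smoothing_points` must be odd.")
  if (!identical(window, "hann")) abort("only the Hann window is supported.")
  bw <- sampling_rate / n_fft
  bins <- selected_hz / bw
  if (any(abs(bins - round(bins)) > 1e-9)) {
    off <- selected_hz[abs(bins - round(bins)) > 1e-9]
    abort(paste0(
      "selected frequencies must be exact multiples of ",
      "sampling_rate/n_fft = ", bw, " Hz; offending: ",
      paste(off, collapse = ", ")
    ))
  }
  bins <- as.integer(round(bins))
  half <- (smoothing_points - 1L) %/% 2L
  if (any(bins - half < 0) || any(bins + half > n_fft %/% 2)) {
    abort("smoothing window runs off the spectrum for some selected bin.")
  }
  structure(
    list(
      n_fft = as.integer(n_fft), overlap = as.integer(overlap),
      hop = as.integer(n_fft - overlap), window = window,
      selected_hz = as.numeric(selected_hz),
      smoothing_points = as.integer(smoothing_points),
      sampling_rate = as.numeric(sampling_rate),
      softfilter_hz = if (is.null(softfilter_hz)) NULL
                      else as.numeric(softfilter_hz),
      bin_width_hz = bw, bins = bins
    ),
    class = "spectral_config"
  )
}

#' Zero-phase software high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward-backward (zero phase)
#' per channel, mirroring the acquisition software's 50-Hz high-pass. DC
#' offsets are removed entirely.
#'
#' @param rec an [emg_recording()].
#' @param cutoff cutoff frequency in Hz; must be below Nyquist.
#' @return the filtered [emg_recording()].
#' @export
software_highpass <- function(rec, cutoff = 50) {
  fs <- sampling_rate(rec)
  if (cutoff >= fs / 2) abort("`cutoff` must be below the Nyquist frequency.")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  m <- rec_matrix(rec)
  # remove the mean first so edge transients cannot leave a DC residual
  filt <- apply(m, 2, function(x) signal::filtfilt(bf, x - mean(x)))
  rec_update(rec, matrix(filt, nrow = nrow(m)))
}

#' Emulate the analog-to-digital converter
#'
#' Maps every sample to the nearest of `2^bits` uniformly spaced codes
#' spanning `v_range` and back to that code's voltage. Out-of-range
#' samples clip to the extreme codes. The code mapping is
#' `round((v - lo) / (hi - lo) * (2^bits - 1))`, so the maximum in-range
#' quantization error is half a step.
#'
#' @param rec an [emg_recording()].
#' @param bits quantization depth (default 12).
#' @param v_range `c(lo, hi)` voltage span (default `c(-2.5, 2.5)`).
#' @return the quantized [emg_recording()].
#' @export
quantize_adc <- function(rec, bits = 12L, v_range = c(-2.5, 2.5)) {
  if (bits < 1) abort("`bits` must be >= 1.")
  lo <- v_range[1]; hi <- v_range[2]
  n_codes <- 2^bits
  m <- rec_matrix(rec)
  code <- round((m - lo) / (hi - lo) * (n_codes - 1))
  code <- pmin(pmax(code, 0), n_codes - 1)
  rec_update(rec, code / (n_codes - 1) * (hi - lo) + lo)
}

hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Sliding-window spectral features
#'
#' Splits each channel into frames of `n_fft` samples starting every
#' `hop = n_fft - overlap` samples (frames that would run past the end are
#' dropped), applies a Hann taper, and takes the one-sided amplitude
#' spectrum. For each selected frequency with bin index `b`, the feature
#' is the mean of the amplitude bins `[b - 2, b + 2]` (5-point smoothing).
#' Features are laid out channel-major: channel 1's 8 frequencies
#' ascending, then channel 2, then channel 3 - 24 values for the default
#' 3-channel configuration, matching the classifier's input layer.
#'
#' @param rec an [emg_recording()].
#' @param cfg a [spectral_config()].
#' @return a tibble with columns `frame_index` (0-based), `frame_time`
#'   (seconds, frame start) and one non-negative feature column per
#'   channel/frequency pair, named `ch<k>_<freq>Hz`. Zero rows (with a
#'   warning) when the recording is shorter than one frame.
#' @examples
#' rec <- emg_recording(matrix(rnorm(3 * 512), ncol = 3))
#' extract_features(rec, spectral_config())
#' @export
extract_features <- function(rec, cfg = spectral_config()) {
  fs <- sampling_rate(rec)
  if (abs(fs - cfg$sampling_rate) > 1e-9) {
    abort("recording and config disagree on the sampling rate.")
  }
  m <- rec_matrix(rec)
  n <- nrow(m)
  n_ch <- ncol(m)
  feat_names <- as.vector(vapply(
    seq_len(n_ch),
    function(ch) sprintf("ch%d_%gHz", ch, cfg$selected_hz),
    character(length(cfg$selected_hz))
  ))
  if (n < cfg$n_fft) {
    warn("recording shorter than one analysis frame; no features.")
    empty <- matrix(numeric(0), 0, length(feat_names),
                    dimnames = list(NULL, feat_names))
    return(dplyr::bind_cols(
      tibble::tibble(frame_index = integer(0), frame_time = numeric(0)),
      tibble::as_tibble(empty)
    ))
  }
  n_frames <- (n - cfg$n_fft) %/% cfg$hop + 1L
  taper <- hann_taper(cfg$n_fft)
  half <- (cfg$smoothing_points - 1L) %/% 2L
  sel <- lapply(cfg$bins, function(b) (b - half):(b + half) + 1L)

  feats <- matrix(0, n_frames, length(feat_names))
  for (i in seq_len(n_frames)) {
    i0 <- (i - 1L) * cfg$hop
    frame <- m[(i0 + 1):(i0 + cfg$n_fft), , drop = FALSE] * taper
    spec <- abs(stats::mvfft(frame))
    for (ch in seq_len(n_ch)) {
      vals <- vapply(sel, function(ix) mean(spec[ix, ch]), numeric(1))
      feats[i, (ch - 1L) * length(sel) + seq_along(sel)] <- vals
    }
  }
  colnames(feats) <- feat_names
  dplyr::bind_cols(
    tibble::tibble(
      frame_index = seq_len(n_frames) - 1L,
      frame_time = (seq_len(n_frames) - 1L) * cfg$hop / fs
    ),
    tibble::as_tibble(feats)
  )
}

# names of the feature columns in a feature tibble
feature_cols <- function(df) {
  grep("^ch[0-9]+_", names(df), value = TRUE)
}

# feature tibble -> plain numeric matrix
feature_matrix <- function(df) {
  m <- as.matrix(df[feature_cols(df)])
  storage.mode(m) <- "double"
  m
}

#' Per-frame mean absolute value (MAV)
#'
#' The average rectified amplitude over non-overlapping windows, per
#' channel: the standard EMG activation-level feature shown to the user
#' during labeling.
#'
#' @param rec an [emg_recording()].
#' @param window window length in samples (> 0).
#' @return a tibble with `frame_index`, `frame_time` and one `mav_ch<k>`
#'   column per channel (volts).
#' @export
compute_mav <- function(rec, window = 256L) {
  if (window <= 0) abort("`window` must be positive.")
  m <- rec_matrix(rec)
  if (window > nrow(m)) abort("`window` longer than the recording.")
  n_frames <- nrow(m) %/% window
  idx <- rep(seq_len(n_frames), each = window)
  mav <- apply(m[seq_len(n_frames * window), , drop = FALSE], 2,
               function(x) tapply(abs(x), idx, mean))
  mav <- matrix(mav, nrow = n_frames)
  colnames(mav) <- paste0("mav_", colnames(rec))
  dplyr::bind_cols(
    tibble::tibble(
      frame_index = seq_len(n_frames) - 1L,
      frame_time = (seq_len(n_frames) - 1L) * window / sampling_rate(rec)
    ),
    tibble::as_tibble(mav)
  )
}
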