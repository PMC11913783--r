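#' Motion class specifications for the synthetic EMG generator
#'
#' Each motion class is modelled as band-limited Gaussian noise: per
#' channel, white noise is shaped by a 4th-order Butterworth band-pass to
#' the class band, normalized to unit RMS, modulated by a per-frame
#' log-normal envelope, and scaled to the class's per-channel RMS gain.
#' Distinct motions differ in their channel-gain patterns, emulating
#' distinct muscle contraction patterns under a 3-channel forearm montage.
#'
#' @param motion_id integer class id.
#' @param channel_gains per-channel RMS amplitude in volts (length =
#'   number of channels). All zeros is allowed only for a rest-like class.
#' @param band `c(low_hz, high_hz)` of dominant energy; default 30-150 Hz,
#'   where most surface-EMG power sits.
#' @param envelope_jitter standard deviation of the log-amplitude
#'   modulation applied per 10-ms frame (fractional variability).
#' @return a `motion_class_spec` list.
#' @export
motion_class_spec <- function(motion_id, channel_gains,
                              band = c(30, 150), envelope_jitter = 0.2) {
  if (any(channel_gains < 0)) abort("`channel_gains` must be >= 0.")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort("`band` must be c(low_hz, high_hz) with 0 < low < high.")
  }
  structure(
    list(
      motion_id = as.integer(motion_id),
      channel_gains = as.numeric(channel_gains),
      band = as.numeric(band),
      envelope_jitter = as.numeric(envelope_jitter)
    ),
    class = "motion_class_spec"
  )
}

#' Default 4-class motion set
#'
#' Rest, full-finger grip, open and pinch: the motion counts reported as
#' practical in clinical pattern-recognition use (3-4 motions including
#' rest). Gain vectors are chosen near-orthogonal across the 3 channels,
#' with a small common baseline for rest; bands sit inside the 20-200 Hz
#' region that carries most surface-EMG energy.
#'
#' @return a named list of [motion_class_spec()]s.
#' @export
default_motion_specs <- function() {
  list(
    rest = motion_class_spec(1L, c(0.02, 0.02, 0.02),
                             band = c(30, 150), envelope_jitter = 0.1),
    grip = motion_class_spec(2L, c(0.50, 0.10, 0.06), band = c(30, 150)),
    open = motion_class_spec(3L, c(0.08, 0.45, 0.12), band = c(40, 200)),
    pinch = motion_class_spec(4L, c(0.15, 0.12, 0.50), band = c(20, 120))
  )
}

#' Electrode-shift perturbation
#'
#' Emulates sensor position shifts and conductivity changes after socket
#' reattachment: from `onset_s` onward, every class's channel-gain vector
#' `g` is replaced by `gain_rotation %*% g`. An identity matrix leaves the
#' session untouched; a permutation swaps channels; a scaled identity
#' attenuates uniformly.
#'
#' @param gain_rotation square numeric matrix (channels x channels),
#'   finite and non-singular.
#' @param onset_s shift onset time in seconds from session start.
#' @return a `shift_perturbation` list.
#' @export
shift_perturbation <- function(gain_rotation, onset_s = 0) {
  gain_rotation <- as.matrix(gain_rotation)
  if (!all(is.finite(gain_rotation))) {
    abort("`gain_rotation` must be finite.")
  }
  if (nrow(gain_rotation) != ncol(gain_rotation) ||
      abs(det(gain_rotation)) < .Machine$double.eps) {
    abort("`gain_rotation` must be square and non-singular.")
  }
  if (onset_s < 0) abort("`onset_s` must be >= 0.")
  structure(list(gain_rotation = gain_rotation, onset_s = onset_s),
            class = "shift_perturbation")
}

#' Session scripts
#'
#' An ordered list of (motion, duration) blocks plus session-level
#' settings: 50-Hz mains pickup amplitude (eastern-Japan commercial power),
#' an optional electrode-shift perturbation, and the RNG seed that makes
#' the session exactly reproducible.
#'
#' @param motions data frame with columns `motion_id` and `duration_s`, or
#'   a vector of motion ids with `duration_s` recycled.
#' @param duration_s block duration(s) in seconds when `motions` is a
#'   plain vector.
#' @param mains_amplitude amplitude in volts of the 50-Hz interference
#'   added to every channel before the analog front end.
#' @param shift optional [shift_perturbation()].
#' @param seed RNG seed for the session.
#' @return a `session_script` list.
#' @export
session_script <- function(motions, duration_s = 1,
                           mains_amplitude = 0.05, shift = NULL,
                           seed = 1L) {
  if (!is.data.frame(motions)) {
    motions <- tibble::tibble(
      motion_id = as.integer(motions),
      duration_s = rep_len(duration_s, length(motions))
    )
  }
  motions <- tibble::as_tibble(motions[c("motion_id", "duration_s")])
  if (any(motions$duration_s <= 0)) abort("block durations must be > 0.")
  if (!is.null(shift) && !inherits(shift, "shift_perturbation")) {
    abort("`shift` must be a shift_perturbation().")
  }
  structure(
    list(
      motions = motions,
      mains_amplitude = as.numeric(mains_amplitude),
      shift = shift,
      seed = as.integer(seed)
    ),
    class = "session_script"
  )
}

# Butterworth band-pass shaping of white noise, unit-RMS normalized.
shape_band_noise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# per-frame log-normal envelope, constant within 10-ms hop blocks
jitter_envelope <- function(n, sdlog, block = 20L) {
  if (sdlog <= 0) return(rep(1, n))
  nb <- ceiling(n / block)
  rep(exp(rnorm(nb, 0, sdlog)), each = block)[seq_len(n)]
}

# causal analog-front-end emulation: 10-400 Hz band-pass + 50-Hz notch
hardware_frontend <- function(x, fs) {
  bp <- signal::butter(4, c(10, 400) / (fs / 2), type = "pass")
  notch <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  as.numeric(signal::filter(notch, signal::filter(bp, x)))
}

#' Generate a synthetic labeled EMG session
#'
#' Runs the session script through the generator: per block and channel,
#' band-shaped unit-RMS Gaussian noise with per-frame envelope jitter is
#' scaled to the class channel gain; 50-Hz mains interference is added;
#' and the analog sensor chain (10-400 Hz band-pass plus 50-Hz notch,
#' applied causally) is emulated before the recording is returned. The
#' label track mirrors the script exactly. The same script (same seed)
#' always yields a bit-identical session; an electrode shift in the script
#' only remixes channel gains from its onset onward, leaving earlier
#' samples untouched.
#'
#' @param specs list of [motion_class_spec()] covering every motion id in
#'   the script.
#' @param script a [session_script()].
#' @param sampling_rate Hz (default 2000).
#' @return a list with elements `recording` ([emg_recording()]) and
#'   `labels` ([label_track()]).
#' @examples
#' ses <- generate_session(
#'   default_motion_specs(),
#'   session_script(c(1, 2), duration_s = 0.5, seed = 7)
#' )
#' duration(ses$recording)
#' @export
generate_session <- function(specs, script, sampling_rate = 2000) {
  fs <- sampling_rate
  spec_ids <- vapply(specs, function(s) s$motion_id, integer(1))
  missing <- setdiff(script$motions$motion_id, spec_ids)
  if (length(missing) > 0) {
    abort(paste0("no motion_class_spec for motion id(s): ",
                 paste(missing, collapse = ", ")))
  }
  n_ch <- length(specs[[1]]$channel_gains)
  for (s in specs) {
    if (length(s$channel_gains) != n_ch) {
      abort("all specs must declare the same number of channels.")
    }
    if (s$band[2] >= fs / 2) abort("class band must lie below Nyquist.")
  }

  ns_blocks <- as.integer(round(script$motions$duration_s * fs))
  n_total <- sum(ns_blocks)
  onset <- if (is.null(script$shift)) n_total else {
    if (script$shift$onset_s > n_total / fs) {
      abort("shift onset lies beyond the session.")
    }
    as.integer(round(script$shift$onset_s * fs))
  }

  samples <- withr::with_seed(script$seed, {
    out <- matrix(0, n_total, n_ch)
    pos <- 0L
    for (b in seq_len(nrow(script$motions))) {
      spec <- specs[[match(script$motions$motion_id[b], spec_ids)]]
      ns <- ns_blocks[b]
      g0 <- spec$channel_gains
      g1 <- if (is.null(script$shift)) g0 else {
        as.numeric(script$shift$gain_rotation %*% g0)
      }
      idx <- pos + seq_len(ns)
      # sample-wise gain: pre-onset original, post-onset remixed
      gains_pre <- (pos + seq_len(ns) - 1L) < onset
      for (ch in seq_len(n_ch)) {
        carrier <- shape_band_noise(ns, spec$band, fs) *
          jitter_envelope(ns, spec$envelope_jitter)
        out[idx, ch] <- carrier * ifelse(gains_pre, g0[ch], g1[ch])
      }
      pos <- pos + ns
    }
    out
  })

  if (script$mains_amplitude > 0) {
    tt <- (seq_len(n_total) - 1) / fs
    samples <- samples + script$mains_amplitude * sin(2 * pi * 50 * tt)
  }
  if (any(samples != 0)) {
    samples <- apply(samples, 2, hardware_frontend, fs = fs)
  }

  ends <- cumsum(ns_blocks)
  labels <- label_track(tibble::tibble(
    start_sample = c(0L, head(ends, -1)),
    end_sample = ends,
    motion_id = script$motions$motion_id
  ))
  rec <- emg_recording(samples, sampling_rate = fs,
                       meta = list(generator = "emgpr synthetic sEMG"))
  attr(rec, "session_script") <- script
  list(recording = rec, labels = labels)
}

#' Re-generate a session under an electrode-shift perturbation
#'
#' Takes a recording produced by [generate_session()] and regenerates it
#' with `shift` applied: same seed, same noise realization, but with every
#' class gain vector remixed by `shift$gain_rotation` from the shift onset
#' onward. Samples before the onset are bit-identical to the input.
#'
#' @param rec an [emg_recording()] from [generate_session()].
#' @param specs the motion class specs the session was generated from.
#' @param shift a [shift_perturbation()].
#' @return the shifted [emg_recording()].
#' @export
apply_shift <- function(rec, specs, shift) {
  script <- attr(rec, "session_script")
  if (is.null(script)) {
    abort("`rec` was not produced by generate_session(); no script stored.")
  }
  if (!inherits(shift, "shift_perturbation")) {
    abort("`shift` must be a shift_perturbation().")
  }
  if (shift$onset_s > duration(rec)) {
    abort("shift onset lies beyond the recording.")
  }
  script$shift <- shift
  generate_session(specs, script, sampling_rate = sampling_rate(rec))$recording
}
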