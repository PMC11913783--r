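test_that("software high-pass rejects DC and low frequencies, keeps the band", {
  fs <- 2000
  n <- 4000
  t <- (0:(n - 1)) / fs
  offset <- emg_recording(matrix(0.7, n, 1), fs)
  out <- software_highpass(offset, 50)
  expect_lt(abs(mean(as.data.frame(out)$ch1)), 0.7 * 1e-6)

  amp_after <- function(freq) {
    rec <- emg_recording(matrix(sin(2 * pi * freq * t), ncol = 1), fs)
    y <- as.data.frame(software_highpass(rec, 50))$ch1
    # steady-state amplitude via RMS away from the edges
    sqrt(2 * mean(y[1001:3000]^2))
  }
  expect_equal(amp_after(200), 1, tolerance = 0.01)
  expect_lt(amp_after(5), 10^(-20 / 20)) # >= 20 dB down
  expect_error(software_highpass(offset, 1000), "Nyquist")
})

test_that("ADC emulation clips to the range and bounds the error by step/2", {
  rec <- emg_recording(matrix(c(3.0, -3.0, -2.5, 2.5, 0), ncol = 1))
  q <- as.data.frame(quantize_adc(rec))$ch1
  expect_equal(q[1], 2.5)
  expect_equal(q[2], -2.5)
  expect_equal(q[3], -2.5)
  expect_equal(q[4], 2.5)

  withr::with_seed(10, {
    v <- runif(10000, -2.5, 2.5)
    qq <- as.data.frame(quantize_adc(emg_recording(matrix(v))))$ch1
    step <- 5 / (2^12 - 1)
    expect_lte(max(abs(qq - v)), step / 2 + 1e-12)
  })
})

test_that("frame count follows floor((n - n_fft)/hop) + 1 and short input warns", {
  cfg <- spectral_config()
  f1 <- extract_features(make_noise_recording(n = 256), cfg)
  expect_equal(nrow(f1), 1)
  f2 <- extract_features(make_noise_recording(n = 276), cfg)
  expect_equal(nrow(f2), 2)
  expect_equal(f2$frame_time, c(0, 0.01))
  expect_warning(
    f0 <- extract_features(make_noise_recording(n = 100), cfg),
    "shorter"
  )
  expect_equal(nrow(f0), 0)
})

test_that("default configuration produces 24-dimensional feature vectors", {
  f <- extract_features(make_noise_recording(n = 512), spectral_config())
  expect_length(grep("^ch", names(f)), 24)
})

test_that("selected frequencies must sit on the FFT grid", {
  expect_error(spectral_config(selected_hz = c(25, 50)), "multiples")
  cfg <- spectral_config()
  expect_equal(cfg$bins, c(3L, 6L, 9L, 12L, 18L, 24L, 32L, 40L))
  expect_equal(cfg$bins * cfg$bin_width_hz, cfg$selected_hz)
})

test_that("a pure on-grid sinusoid lights up exactly its channel/frequency bin", {
  fs <- 2000
  t <- (0:1023) / fs
  rec <- emg_recording(cbind(0, sin(2 * pi * 93.75 * t), 0), fs)
  f <- extract_features(rec, spectral_config())
  nm <- grep("^ch", names(f), value = TRUE)
  v <- as.numeric(f[1, nm])
  expect_equal(nm[which.max(v)], "ch2_93.75Hz")
  expect_equal(max(v[grepl("ch1|ch3", nm)]), 0, tolerance = 1e-10)
  # closed form for a 256-sample Hann frame: unit sinusoid on bin b has
  # |X[b]| = n/4 and |X[b +/- 1]| = n/8, zero beyond -> 5-bin mean = n/10
  expect_equal(max(v), 256 / 10, tolerance = 1e-6)
})

test_that("features are homogeneous of degree 1 and vanish on silence", {
  rec <- make_noise_recording(n = 700, seed = 6)
  cfg <- spectral_config()
  f1 <- extract_features(rec, cfg)
  f2 <- extract_features(rec_x2 <- emg_recording(
    2 * as.matrix(as.data.frame(rec)), 2000), cfg)
  m1 <- as.matrix(f1[grep("^ch", names(f1))])
  m2 <- as.matrix(f2[grep("^ch", names(f2))])
  expect_true(all(m1 >= 0))
  expect_equal(m2, 2 * m1, tolerance = 1e-9)

  z <- extract_features(emg_recording(matrix(0, 256, 3)), cfg)
  expect_true(all(as.matrix(z[grep("^ch", names(z))]) == 0))
})

test_that("MAV matches its definition on constant and alternating signals", {
  rec <- emg_recording(cbind(rep(0.25, 8), c(1, -1, 1, -1, 1, -1, 1, -1)))
  mav <- compute_mav(rec, window = 4)
  expect_equal(mav$mav_ch1, c(0.25, 0.25))
  expect_equal(mav$mav_ch2, c(1, 1))
  expect_error(compute_mav(rec, window = 0), "positive")
})

test_that("active-class MAV exceeds rest MAV on generated sessions", {
  specs <- default_motion_specs()
  ses <- generate_session(specs, session_script(c(1, 2), duration_s = 1.5,
                                                seed = 13))
  mav <- compute_mav(ses$recording, window = 20)
  rest <- mav$mav_ch1[mav$frame_index < 150]
  grip <- mav$mav_ch1[mav$frame_index >= 150]
  expect_gte(length(rest), 100)
  expect_gt(mean(grip), mean(rest))
})
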