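test_that("generation is exactly reproducible under a fixed seed", {
  specs <- default_motion_specs()
  script <- session_script(c(1, 2, 3), duration_s = 0.5, seed = 9)
  a <- generate_session(specs, script)
  b <- generate_session(specs, script)
  expect_identical(as.data.frame(a$recording), as.data.frame(b$recording))
  expect_identical(as.data.frame(a$labels), as.data.frame(b$labels))
})

test_that("label track mirrors the script and matches the sample count", {
  specs <- default_motion_specs()
  ses <- generate_session(specs,
    session_script(c(2, 1, 4), duration_s = c(0.5, 0.25, 1), seed = 1))
  expect_equal(ses$labels$motion_id, c(2L, 1L, 4L))
  expect_equal(ses$labels$end_sample, cumsum(c(1000L, 500L, 2000L)))
  expect_equal(nrow(ses$recording), 3500)
})

test_that("a silent rest class with no mains yields an all-zero segment", {
  spec <- list(motion_class_spec(1L, c(0, 0, 0)))
  ses <- generate_session(spec,
    session_script(1, duration_s = 0.5, mains_amplitude = 0, seed = 4))
  expect_true(all(as.matrix(as.data.frame(ses$recording)) == 0))
})

test_that("generated class energy concentrates in the declared band", {
  spec <- list(motion_class_spec(1L, c(0.3, 0.3, 0.3), band = c(30, 150)))
  ses <- generate_session(spec,
    session_script(1, duration_s = 5, mains_amplitude = 0, seed = 2))
  x <- as.matrix(as.data.frame(ses$recording))[, 1]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 2000), spans = 11,
                          plot = FALSE, taper = 0)
  band_power <- function(lo, hi) {
    mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
  }
  expect_gt(band_power(30, 150) / band_power(300, 500), 10)
})

test_that("rest produces lower MAV than every active class", {
  specs <- default_motion_specs()
  ses <- generate_session(specs,
    session_script(1:4, duration_s = 1.5, seed = 8))
  mav <- compute_mav(ses$recording, window = 20)
  lab <- findInterval(mav$frame_index * 20, ses$labels$start_sample)
  total <- rowSums(as.matrix(mav[grep("^mav_", names(mav))]))
  means <- tapply(total, lab, mean)
  expect_gte(min(table(lab)), 100) # enough frames per class
  expect_true(all(means["1"] < means[c("2", "3", "4")]))
})

test_that("unknown motions and bad durations are rejected", {
  specs <- default_motion_specs()
  expect_error(
    generate_session(specs, session_script(c(1, 9), duration_s = 0.5)),
    "motion id"
  )
  expect_error(session_script(1, duration_s = -1), "durations")
})

test_that("identity shift leaves the session bit-identical", {
  specs <- default_motion_specs()
  ses <- generate_session(specs, session_script(c(2, 3), duration_s = 0.5,
                                                seed = 5))
  shifted <- apply_shift(ses$recording, specs,
                         shift_perturbation(diag(3), onset_s = 0.5))
  expect_identical(emgpr:::rec_matrix(shifted),
                   emgpr:::rec_matrix(ses$recording))
})

test_that("a channel-swap shift swaps the post-onset RMS profile", {
  specs <- default_motion_specs()
  ses <- generate_session(specs,
    session_script(c(2, 2), duration_s = 1, mains_amplitude = 0, seed = 5))
  sw <- shift_perturbation(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3,
                                  byrow = TRUE), onset_s = 1)
  shifted <- apply_shift(ses$recording, specs, sw)
  m0 <- as.matrix(as.data.frame(ses$recording))
  m1 <- as.matrix(as.data.frame(shifted))
  expect_identical(m0[1:2000, ], m1[1:2000, ]) # pre-onset untouched
  rms <- function(m) sqrt(colMeans(m^2))
  post0 <- rms(m0[2001:4000, ])
  post1 <- rms(m1[2001:4000, ])
  expect_equal(unname(post1[1]), unname(post0[2]), tolerance = 0.05)
  expect_equal(unname(post1[2]), unname(post0[1]), tolerance = 0.05)
})

test_that("a 0.5-identity shift halves the post-onset RMS within 5%", {
  specs <- default_motion_specs()
  ses <- generate_session(specs,
    session_script(c(2, 2), duration_s = 1, mains_amplitude = 0, seed = 5))
  half <- apply_shift(ses$recording, specs,
                      shift_perturbation(0.5 * diag(3), onset_s = 1))
  m0 <- as.matrix(as.data.frame(ses$recording))
  mh <- as.matrix(as.data.frame(half))
  rms <- function(m) sqrt(colMeans(m^2))
  expect_equal(unname(rms(mh[2001:4000, ]) / rms(m0[2001:4000, ])),
               rep(0.5, 3), tolerance = 0.05)
})

test_that("degenerate shifts are rejected", {
  expect_error(shift_perturbation(matrix(0, 3, 3)), "non-singular")
  expect_error(shift_perturbation(matrix(NaN, 3, 3)), "finite")
  specs <- default_motion_specs()
  ses <- generate_session(specs, session_script(1, duration_s = 0.5))
  expect_error(
    apply_shift(ses$recording, specs,
                shift_perturbation(diag(3), onset_s = 2)),
    "beyond"
  )
})
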