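# shared fixtures, all generated in code

make_noise_recording <- function(n = 1024, channels = 3, fs = 2000,
                                 seed = 1, scale = 0.1) {
  withr::with_seed(seed, {
    emg_recording(matrix(rnorm(n * channels, sd = scale), ncol = channels),
                  sampling_rate = fs)
  })
}

# two well-separated 24-D Gaussian clusters, feature-style column names
separable_teacher <- function(n_per_class = 100, seed = 42, sep = 1.5) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per_class * 24, 0), n_per_class),
      matrix(rnorm(n_per_class * 24, sep), n_per_class)
    )
    colnames(x) <- sprintf("ch%d_%gHz", rep(1:3, each = 8),
                           rep(1:8, 3) * 7.8125)
    dplyr::bind_cols(
      tibble::as_tibble(x),
      tibble::tibble(motion_id = rep(1:2, each = n_per_class))
    )
  })
}

# independent count-and-argmax vote (tie -> smallest id), for oracles
brute_vote <- function(entries, classes = sort(unique(entries))) {
  counts <- vapply(classes, function(cl) sum(entries == cl), integer(1))
  classes[which.max(counts)]
}

channel_swap_12 <- function() {
  shift_perturbation(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
                     onset_s = 0)
}
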