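test_that("teacher labeling buffers exactly the requested frame count", {
  feats <- extract_features(make_noise_recording(n = 2700), spectral_config())
  expect_gte(nrow(feats), 120)
  lab <- label_teacher_data(feats, motion_id = 3, frames_per_class = 100)
  expect_equal(nrow(lab), 100)
  expect_true(all(lab$motion_id == 3L))
  expect_error(
    label_teacher_data(feats[0, ], motion_id = 1, frames_per_class = 10),
    "0 frames collected"
  )
})

test_that("labeling four motions at 100 frames each covers all classes", {
  teacher <- purrr::map_dfr(1:4, function(id) {
    feats <- extract_features(make_noise_recording(n = 2700, seed = id),
                              spectral_config())
    label_teacher_data(feats, id, 100)
  })
  expect_equal(nrow(teacher), 400)
  expect_equal(sort(unique(teacher$motion_id)), 1:4)
  expect_equal(unname(table(teacher$motion_id)), rep(100L, 4),
               ignore_attr = TRUE)
})

test_that("training separates two Gaussian clusters perfectly within 500 epochs", {
  teacher <- separable_teacher()
  fit <- train_ann(teacher, epochs = 500, seed = 3)
  expect_equal(mean(predict(fit, teacher)$.pred == teacher$motion_id), 1)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
})

test_that("training is deterministic under a fixed seed", {
  teacher <- separable_teacher(n_per_class = 30)
  f1 <- train_ann(teacher, epochs = 50, seed = 11)
  f2 <- train_ann(teacher, epochs = 50, seed = 11)
  expect_identical(f1$weights, f2$weights)
})

test_that("full-batch loss is non-increasing over the final epochs", {
  teacher <- separable_teacher(n_per_class = 50)
  fit <- train_ann(teacher, epochs = 300, batch = "full", seed = 2)
  tail_loss <- tail(fit$loss_trace, 30)
  expect_true(all(diff(tail_loss) <= 1e-10))
})

test_that("analytic gradients match central differences", {
  teacher <- separable_teacher(n_per_class = 10)
  fit <- train_ann(teacher, epochs = 5, seed = 7)
  w <- fit$weights
  withr::with_seed(1, {
    xn <- matrix(runif(4 * 24), 4)
    tg <- matrix(0, 4, 2)
    tg[cbind(1:4, sample(1:2, 4, TRUE))] <- 1
  })
  g <- emgpr:::ann_loss_grad(w, xn, tg, 2)
  h <- 1e-6
  for (part in c("w1", "b1", "w2", "b2")) {
    num <- w[[part]] * 0
    for (i in seq_along(num)) {
      wp <- w; wp[[part]][i] <- wp[[part]][i] + h
      wm <- w; wm[[part]][i] <- wm[[part]][i] - h
      num[i] <- (emgpr:::ann_loss_grad(wp, xn, tg, 2)$loss -
                 emgpr:::ann_loss_grad(wm, xn, tg, 2)$loss) / (2 * h)
    }
    rel <- abs(num - g[[part]]) / pmax(abs(num), 1e-4)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("a single-class teacher set always predicts that class", {
  teacher <- separable_teacher(n_per_class = 40)
  teacher$motion_id <- 5L
  fit <- train_ann(teacher, epochs = 50, seed = 1)
  expect_true(all(predict(fit, teacher)$.pred == 5L))
})

test_that("more classes than output neurons is an error", {
  teacher <- separable_teacher(n_per_class = 9)
  teacher$motion_id <- rep(1:9, 2)
  expect_error(train_ann(teacher), "output-layer neurons")
})

test_that("all-zero weights and inputs tie every output; vote goes to smallest id", {
  teacher <- separable_teacher(n_per_class = 20)
  fit <- train_ann(teacher, epochs = 1, seed = 1)
  fit$weights$w1[] <- 0; fit$weights$b1[] <- 0
  fit$weights$w2[] <- 0; fit$weights$b2[] <- 0
  x <- matrix(0, 1, 24)
  p <- predict(fit, x)
  expect_equal(as.numeric(p[1, -1]), rep(0.5, 2)) # sigmoid(0) everywhere
  expect_equal(p$.pred, min(fit$class_map))
})

test_that("prediction ignores unassigned output slots", {
  teacher <- separable_teacher(n_per_class = 30)
  fit <- train_ann(teacher, epochs = 100, seed = 4)
  before <- predict(fit, teacher)
  fit$weights$w2[, 3:8] <- 100 # clobber untrained slots
  fit$weights$b2[3:8] <- 100
  after <- predict(fit, teacher)
  expect_identical(before, after)
})

test_that("wrong feature length is rejected at prediction", {
  fit <- train_ann(separable_teacher(n_per_class = 10), epochs = 2, seed = 1)
  expect_error(predict(fit, matrix(0, 1, 10)), "feature length")
})

test_that("parameters survive a JSON round-trip bit-exactly", {
  teacher <- separable_teacher(n_per_class = 30)
  fit <- train_ann(teacher, epochs = 100, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_params(fit, path)
  back <- load_params(path)
  expect_equal(back$class_map, fit$class_map)
  withr::with_seed(2, {
    x <- matrix(runif(100 * 24, 0, 30), 100)
  })
  expect_identical(predict(back, x), predict(fit, x))

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(load_params(path))
})

test_that("an independent MLP implementation solves the same fixture", {
  teacher <- separable_teacher()
  fit <- train_ann(teacher, epochs = 500, seed = 3)
  x <- as.data.frame(scale(as.matrix(teacher[grep("^ch", names(teacher))])))
  targets <- stats::model.matrix(~ 0 + factor(teacher$motion_id))
  ref <- withr::with_seed(1, nnet::nnet(x, targets, size = 4,
                                        trace = FALSE, maxit = 200))
  ref_pred <- max.col(predict(ref, x))
  expect_equal(mean(ref_pred == teacher$motion_id), 1)
  expect_equal(mean(predict(fit, teacher)$.pred == teacher$motion_id), 1)
})

test_that("tidy and glance summarize the fitted network", {
  fit <- train_ann(separable_teacher(n_per_class = 10), epochs = 5, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 24 * 32 + 32 + 32 * 8 + 8)
  gl <- glance(fit)
  expect_equal(gl$n_classes, 2)
  expect_lte(gl$final_loss, gl$initial_loss)
})
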