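test_that("out-of-range hyperparameters are rejected", {
  expect_error(classifier_config(learning_rate = 1), "learning_rate")
  expect_error(classifier_config(num_filters_1 = 5), "num_filters_1")
  expect_error(classifier_config(dropout_rate = 0.7), "dropout_rate")
  expect_error(classifier_config(batch_size = 10), "batch_size")
  expect_error(classifier_config(l2_reg = 1), "l2_reg")
  # l2_reg = 0 (no regularization) is explicitly allowed
  expect_s3_class(classifier_config(l2_reg = 0), "classifier_config")
  expect_error(classifier_config(epochs = 0), "epochs")
})

test_that("model building is deterministic and counts parameters analytically", {
  cfg <- classifier_config("cnn", num_filters_1 = 12, num_filters_2 = 24,
                           dense_units = 64, seed = 7)
  m1 <- build_model(cfg, c(64, 2))
  m2 <- build_model(cfg, c(64, 2))
  expect_identical(m1$params, m2$params)
  expect_equal(n_parameters(m1), n_parameters(m2))

  # cnn conv parameters: k1*C*f1 + f1 + k2*f1*f2 + f2
  expect_equal(n_parameters(m1, convolutional_only = TRUE),
               7 * 2 * 12 + 12 + 5 * 12 * 24 + 24)
  mm <- build_model(classifier_config("mlcnn", num_filters_1 = 12,
                                      num_filters_2 = 24, dense_units = 64,
                                      seed = 7), c(64, 2))
  expect_equal(n_parameters(mm, convolutional_only = TRUE),
               (3 + 9 + 27) * 2 * 12 + 3 * 12)
  # at the standard 450 x 11 input and equal filter settings the three
  # streams hold more convolution parameters than the cnn stack
  cnn_std <- build_model(classifier_config("cnn", seed = 1))
  ml_std <- build_model(classifier_config("mlcnn", seed = 1))
  expect_gt(n_parameters(ml_std, convolutional_only = TRUE),
            n_parameters(cnn_std, convolutional_only = TRUE))
})

test_that("softmax output is a probability vector over the 9 classes", {
  cfg <- classifier_config("mlcnn", num_filters_1 = 10, dense_units = 64,
                           seed = 2)
  m <- build_model(cfg, c(64, 2))
  w <- toy_windows(n_per_class = 2, seed = 5)
  p <- predict(m, w)
  probs <- as.matrix(p[, paste0("p", 0:8)])
  expect_equal(rowSums(probs), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_true(all(p$code %in% 0:8))
})

test_that("prediction is invariant to batch context and checks shapes", {
  cfg <- classifier_config("cnn", num_filters_1 = 10, num_filters_2 = 20,
                           dense_units = 64, seed = 3)
  m <- build_model(cfg, c(64, 2))
  w <- toy_windows(n_per_class = 5, seed = 8)
  all_at_once <- predict(m, w)
  one_by_one <- dplyr::bind_rows(lapply(seq_len(nrow(w)), function(i) {
    predict(m, w[i, ])
  }))
  expect_equal(as.data.frame(all_at_once), as.data.frame(one_by_one),
               tolerance = 1e-12)
  bad <- toy_windows(n_per_class = 1, L = 32)
  expect_error(predict(m, bad), "shape")
})

test_that("training learns a separable toy problem and records history", {
  w <- toy_windows(n_per_class = 30, codes = c(0L, 3L), seed = 1)
  cfg <- classifier_config("cnn", learning_rate = 3e-3, num_filters_1 = 10,
                           num_filters_2 = 20, dense_units = 64,
                           dropout_rate = 0.1, batch_size = 32, epochs = 15,
                           seed = 4)
  m <- build_model(cfg, c(64, 2))
  expect_warning(mt <- train_model(m, w, validation_fraction = 0),
                 "absent")
  expect_gte(utils::tail(mt$history$accuracy, 1), 0.99)
  # without early stopping the history spans all epochs
  expect_equal(nrow(mt$history), 15)
  expect_equal(mt$history$epoch, 1:15)
  expect_error(train_model(m, w[0, ]), "empty")
})

test_that("training is deterministic under a fixed seed", {
  w <- toy_windows(n_per_class = 10, codes = c(0L, 1L, 3L), seed = 2)
  cfg <- classifier_config("mlcnn", num_filters_1 = 10, dense_units = 64,
                           dropout_rate = 0.1, batch_size = 32, epochs = 3,
                           seed = 9)
  m1 <- suppressWarnings(train_model(build_model(cfg, c(64, 2)), w))
  m2 <- suppressWarnings(train_model(build_model(cfg, c(64, 2)), w))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("confusion matrix accounting is exact", {
  truth <- c(0, 0, 3, 4, 4, 7)
  pred <- c(0, 3, 3, 4, 3, 7)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 6)
  expect_equal(accuracy(cm), 4 / 6)
  expect_equal(cm["0", "3"], 1)
  expect_equal(cm["4", "3"], 1)
  td <- tidy(cm)
  expect_equal(sum(td$n), 6)
})

test_that("group cross-validation keeps folds disjoint and covers groups", {
  w <- toy_windows(n_per_class = 12, codes = c(0L, 2L, 6L), C = 3,
                   groups = 1:3, seed = 3)
  cfg <- classifier_config("cnn", learning_rate = 3e-3, num_filters_1 = 10,
                           num_filters_2 = 20, dense_units = 64,
                           dropout_rate = 0.1, batch_size = 32, epochs = 8,
                           seed = 5)
  cv <- suppressWarnings(crossval_groups(w, cfg, seed = 5))
  expect_equal(nrow(cv), 3)
  expect_setequal(cv$group, 1:3)
  for (i in seq_len(nrow(cv))) {
    n_ext <- sum(w$group == cv$group[i])
    expect_equal(cv$n_external[i], n_ext)
    expect_equal(cv$n_train[i], nrow(w) - n_ext)
    expect_equal(sum(cv$confusion[[i]]), n_ext)
  }
  g <- glance(cv)
  expect_equal(g$n_folds, 3)
  # exchangeable easy groups: internal and external accuracies agree
  expect_lt(abs(g$mean_internal_accuracy - g$mean_external_accuracy), 0.1)
  expect_error(crossval_groups(w[w$group == 1, ], cfg), "2 distinct")
})

test_that("hyperparameter search respects bounds and logs trials", {
  w <- toy_windows(n_per_class = 8, codes = c(0L, 3L), seed = 6)
  expect_error(search_hyperparameters(w, n_trials = 0), "n_trials")
  hs <- suppressWarnings(
    search_hyperparameters(w, n_trials = 4, epochs = 1, seed = 11)
  )
  sp <- myointent:::hyperparameter_space()
  tr <- tidy(hs)
  expect_equal(nrow(tr), 4)
  for (nm in names(sp)) {
    expect_true(all(tr[[nm]] >= sp[[nm]][1] & tr[[nm]] <= sp[[nm]][2]))
  }
  expect_equal(hs$best_accuracy, max(tr$accuracy))
  expect_s3_class(hs$best_config, "classifier_config")
  expect_equal(sum(hs$importance), 1, tolerance = 1e-9)
  expect_setequal(names(hs$importance), names(sp))
})

test_that("errors concentrate between adjacent directions under tuning drift", {
  # an inter-session rotation of the muscle tuning creates overlap between
  # neighboring direction classes: class 3 (+x) is then confused with its
  # 45-degree neighbor (4) and not with the opposite direction (7)
  rotated <- function(ang) {
    base <- muscle_tuning()
    muscle_tuning(preferred_angle = base$preferred_angle - ang)
  }
  p <- semg_protocol(15)
  train_recs <- lapply(1:3, function(i) {
    synthesize_recording(p, muscle_tuning(), noise_spec(), seed = i,
                         meta = list(subject = 1L, group = 1L))
  })
  test_recs <- lapply(4:5, function(i) {
    synthesize_recording(p, rotated(0.3), noise_spec(), seed = 10 + i,
                         meta = list(subject = 1L, group = 2L))
  })
  bind_windows <- function(recs) {
    out <- dplyr::bind_rows(lapply(recs, segment_windows))
    class(out) <- c("labeled_windows", class(out))
    out
  }
  wtr <- bind_windows(train_recs)
  wte <- bind_windows(test_recs)
  cfg <- classifier_config("mlcnn", epochs = 5, seed = 3)
  m <- suppressWarnings(train_model(build_model(cfg, dim(wtr$samples[[1]])), wtr))
  cm <- confusion_matrix(wte$label, predict(m, wte)$code)
  expect_gt(cm["3", "4"] + cm["4", "3"], cm["3", "7"] + cm["7", "3"])
  # adjacent-pair confusions dominate opposite-pair confusions overall
  adjacent <- sum(vapply(1:8, function(k) {
    kk <- k %% 8 + 1
    cm[as.character(k), as.character(kk)] + cm[as.character(kk), as.character(k)]
  }, numeric(1)))
  opposite <- sum(vapply(1:4, function(k) {
    kk <- ((k + 3) %% 8) + 1
    cm[as.character(k), as.character(kk)] + cm[as.character(kk), as.character(k)]
  }, numeric(1)))
  expect_gt(adjacent, opposite)
})

test_that("checkpoints round-trip through plain-text serialization", {
  w <- toy_windows(n_per_class = 6, codes = c(0L, 5L), seed = 12)
  cfg <- classifier_config("mlcnn", num_filters_1 = 10, dense_units = 64,
                           dropout_rate = 0.1, batch_size = 32, epochs = 2,
                           seed = 3)
  m <- suppressWarnings(train_model(build_model(cfg, c(64, 2)), w))
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(predict(m2, w), predict(m, w), tolerance = 1e-12)
  expect_equal(m2$history$loss, m$history$loss, tolerance = 1e-9)
})
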