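test_that("architecture census honors the layer-count contracts", {
  cnn <- build_model(model_spec("cnn"), seed = 1)
  cc <- layer_census(cnn)
  expect_equal(cc$conv_layers, 6L)
  expect_equal(cc$fc_layers, 2L)
  expect_equal(cc$penultimate_width, 64L)
  expect_equal(cc$output_classes, 2L)

  icnn <- build_model(model_spec("icnn"), seed = 1)
  ic <- layer_census(icnn)
  expect_equal(ic$conv_layers, 2L)
  expect_equal(ic$inception_modules, 2L)
  expect_equal(ic$penultimate_width, 64L)

  rf <- build_model(model_spec("rf"), seed = 1)
  rc <- layer_census(rf)
  expect_equal(rc$n_trees, 200L)
  expect_equal(rc$mtry, 29L)          # floor(sqrt(850))
  expect_equal(floor(sqrt(850)), 29)

  expect_error(model_spec("cnn", fc_widths = c(256, 32)), "64 nodes")
  expect_error(model_spec("cnn", cnn_channels = c(8, 16)), "6 conv")
})

test_that("probability outputs are valid two-class distributions", {
  sh <- shared_cnn_fit()
  p <- predict(sh$fit, sh$test)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_identical(colnames(p), c("good", "bad"))
  cls <- predict(sh$fit, sh$test, type = "class")
  expect_true(all(cls %in% c("good", "bad")))

  # duplicated input rows give identical probabilities
  X <- sh$test$spectra[c(1, 1, 2), ]
  pd <- predict(sh$fit, X)
  expect_identical(pd[1, ], pd[2, ])
})

test_that("untrained models refuse to predict and inputs are length-checked", {
  cnn <- build_model(small_spec("cnn"), seed = 1)
  X <- matrix(rnorm(2 * 850), 2, 850)
  expect_error(predict(cnn, X), "not been fitted")
  rf <- build_model(model_spec("rf"), seed = 1)
  expect_error(predict(rf, X), "not been fitted")

  sh <- shared_cnn_fit()
  expect_error(predict(sh$fit, matrix(rnorm(2 * 512), 2, 512)),
               "850-point")
})

test_that("penultimate features are 64-wide, deterministic and consistent", {
  sh <- shared_cnn_fit()
  X <- sh$test$spectra[1:10, ]
  f1 <- extract_penultimate_features(sh$fit, X)
  expect_equal(dim(f1), c(10L, 64L))
  expect_identical(f1, extract_penultimate_features(sh$fit, X))

  # features through the model's own output head reproduce predict()
  head_layer <- sh$fit$net$layers[[length(sh$fit$net$layers)]]
  logits <- f1 %*% head_layer$params$W +
    rep(head_layer$params$b, each = nrow(f1))
  manual <- exp(logits) / rowSums(exp(logits))
  expect_equal(unname(manual), unname(predict(sh$fit, X)), tolerance = 1e-6)

  rf <- qc_fit(sh$cohort, kind = "rf", seed = 2)
  expect_error(extract_penultimate_features(rf, X), "network models")
})

test_that("hybrids fit a 200-tree forest on exactly 64 deep features", {
  sh <- shared_cnn_fit()
  hy <- build_hybrid(sh$fit, sh$cohort, seed = 4)
  hc <- layer_census(hy)
  expect_equal(hc$n_trees, 200L)
  expect_equal(hc$rf_input_features, 64L)
  expect_equal(hy$rf_mtry, 8L)        # floor(sqrt(64))
  expect_equal(hc$base$conv_layers, 6L)

  p <- predict(hy, sh$test)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
  # training accuracy on separable features is essentially perfect
  p_tr <- predict(hy, sh$cohort)[, "good"]
  expect_gte(qc_accuracy(sh$cohort$manifest$consensus, p_tr), 0.99)

  untrained <- build_model(small_spec("cnn"), seed = 1)
  expect_error(build_hybrid(untrained, sh$cohort), "trained")

  hy2 <- build_hybrid(sh$fit, sh$cohort, seed = 4)
  expect_identical(predict(hy2, sh$test), predict(hy, sh$test))
})

test_that("a single-tree forest recovers the optimal stump on separable data", {
  set.seed(31)
  n <- 60
  x1 <- c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1))  # separable feature
  X <- cbind(x1, matrix(runif(n * 63), n, 64 - 1))
  y <- rep(c("bad", "good"), each = n / 2)
  spec <- model_spec("rf", input_length = 64, rf_n_estimators = 1,
                     rf_max_features = 64)
  fit <- qc_fit(X, y, spec = spec, seed = 7)
  pred <- predict(fit, X, type = "class")

  # exhaustive stump search over every feature and midpoint threshold
  best_err <- Inf; best_pred <- NULL
  for (j in seq_len(ncol(X))) {
    cuts <- sort(unique(X[, j]))
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cc in cuts) for (dir in c(1, -1)) {
      p <- ifelse(dir * X[, j] > dir * cc, "good", "bad")
      err <- mean(p != y)
      if (err < best_err) { best_err <- err; best_pred <- p }
    }
  }
  expect_equal(best_err, 0)
  expect_identical(pred, best_pred)
})

test_that("RF training is seed-deterministic and rejects one-class labels", {
  coh <- quick_cohort(n_subjects = 3, voxels = 20, seed = 33)
  a <- qc_fit(coh, kind = "rf", seed = 11)
  b <- qc_fit(coh, kind = "rf", seed = 11)
  expect_identical(predict(a, coh), predict(b, coh))
  expect_error(qc_fit(coh$spectra, rep("good", nrow(coh$spectra)),
                      kind = "rf"),
               "single-class")
})

test_that("model archives round-trip through save/load", {
  sh <- shared_cnn_fit()
  path <- file.path(tempdir(), "model.bin")
  save_qc_model(sh$fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_qc_model(path)
  expect_identical(predict(back, sh$test), predict(sh$fit, sh$test))
  unlink(c(path, paste0(path, ".json")))
})
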