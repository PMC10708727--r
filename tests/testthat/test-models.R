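spec_for <- function(ds, name = "cnn_lstm", seed = 1L) {
  model_spec(name, dim(ds$X)[2], dim(ds$X)[3], sort(unique(ds$labels)),
             filters = 4L, units = 4L, seed = seed)
}

test_that("layer stacks match the declared architectures", {
  ds <- fake_dataset(4)
  m6 <- build_architecture(spec_for(ds, "cnn_lstm"))
  expect_identical(architecture_layers(m6),
                   c("input", "conv1", "conv2", "lstm1", "lstm2",
                     "dense_softmax"))
  expect_length(architecture_layers(m6), 6L)
  m8 <- build_architecture(spec_for(ds, "deepconvlstm"))
  expect_identical(architecture_layers(m8),
                   c("input", "conv1", "conv2", "conv3", "conv4",
                     "lstm1", "lstm2", "dense_softmax"))
  expect_length(architecture_layers(m8), 8L)
  mr <- build_architecture(spec_for(ds, "resnet"))
  expect_identical(architecture_layers(mr),
                   c("input", "block1", "block2", "gap", "dense_softmax"))
  # each residual block carries conv x3 + batch-norm (+ skip projection)
  expect_identical(mr$layers$block1$conv3$activation, "linear")
  expect_identical(mr$layers$block1$bn$type, "batchnorm")
  expect_false(is.null(mr$layers$block1$proj))  # 3 features -> 4 filters
  expect_null(mr$layers$block2$proj)            # identity skip, equal widths
  # output width equals the class count everywhere
  for (m in list(m6, m8, mr)) {
    expect_identical(ncol(m$layers$dense_softmax$params$W), 2L)
  }
  expect_error(model_spec("transformer", 4, 3, c("a", "b")), "arg")
})

test_that("initialization is deterministic under the spec seed", {
  ds <- fake_dataset(4)
  for (arch in c("cnn_lstm", "resnet", "deepconvlstm")) {
    a <- build_architecture(spec_for(ds, arch, seed = 7L))
    b <- build_architecture(spec_for(ds, arch, seed = 7L))
    expect_identical(harkit:::.model_params(a), harkit:::.model_params(b))
    c2 <- build_architecture(spec_for(ds, arch, seed = 8L))
    expect_false(identical(harkit:::.model_params(a),
                           harkit:::.model_params(c2)))
  }
})

test_that("zero epochs and full freezing leave parameters untouched", {
  ds <- separable_dataset(6)
  m <- build_architecture(spec_for(ds))
  m0 <- train(m, ds, epochs = 0)
  expect_identical(harkit:::.model_params(m0), harkit:::.model_params(m))
  frozen <- m
  frozen$trainable[] <- FALSE
  mf <- train(frozen, ds, epochs = 3, lr = 1e-2)
  expect_identical(harkit:::.model_params(mf), harkit:::.model_params(m))
  expect_error(train(m, fake_dataset(4, window_len = 5L), 1), "shape")
})

test_that("training reduces the loss on a separable problem", {
  ds <- separable_dataset(8)
  for (arch in c("cnn_lstm", "resnet", "deepconvlstm")) {
    m <- train(build_architecture(spec_for(ds, arch, seed = 2L)), ds,
               epochs = 12, lr = 1e-2, batch_size = 8)
    expect_length(m$log, 12L)
    expect_lt(m$log[12], m$log[1])
    # post-training accuracy beats chance on the training windows
    pr <- predict(m, ds)
    expect_gt(mean(pr$labels == ds$labels), 0.5)
  }
})

test_that("training is deterministic for a fixed seed and dataset", {
  ds <- separable_dataset(5)
  m1 <- train(build_architecture(spec_for(ds, seed = 3L)), ds, 3, lr = 1e-3)
  m2 <- train(build_architecture(spec_for(ds, seed = 3L)), ds, 3, lr = 1e-3)
  expect_identical(harkit:::.model_params(m1), harkit:::.model_params(m2))
  expect_identical(m1$log, m2$log)
})

test_that("the training loss is the categorical cross-entropy", {
  set.seed(6)
  scores <- matrix(rnorm(12), 3, 4)
  targets <- c(2L, 4L, 1L)
  expect_equal(harkit:::.ce_batch(scores, targets),
               mean(vapply(1:3, function(i) cross_entropy(scores[i, ], targets[i]),
                           numeric(1))),
               tolerance = 1e-12)
})

test_that("window classification returns a proper distribution", {
  ds <- separable_dataset(5)
  m <- train(build_architecture(spec_for(ds)), ds, 2, lr = 1e-3)
  w <- ds$X[1, , ]
  r <- classify_window(m, w)
  expect_equal(sum(r$probabilities), 1, tolerance = 1e-6)
  expect_true(all(r$probabilities >= 0))
  expect_identical(r$label, names(which.max(r$probabilities)))
  expect_identical(classify_window(m, w), classify_window(m, w))
  expect_error(classify_window(m, w[-1, ]), "shape")
  # sentinel -1 entries are legal input
  w[, 1] <- -1
  expect_equal(sum(classify_window(m, w)$probabilities), 1, tolerance = 1e-6)
})

test_that("fine-tuning only ever touches the final dense layer", {
  ds <- separable_dataset(10, seed = 4)
  m <- train(build_architecture(spec_for(ds)), ds, 3, lr = 1e-3)
  ft <- fine_tune(m, ds, epochs = 4, batch_size = 7, seed = 2)
  p_before <- harkit:::.model_params(m)
  p_after <- harkit:::.model_params(ft$model)
  head <- grepl("^dense_softmax", names(p_before))
  expect_identical(p_after[!head], p_before[!head])   # bitwise frozen
  expect_false(identical(p_after[head], p_before[head]))
  # trainable flags are restored afterwards
  expect_identical(ft$model$trainable, m$trainable)
  # zero-epoch fine-tuning changes nothing at all
  ft0 <- fine_tune(m, ds, epochs = 0, seed = 2)
  expect_identical(harkit:::.model_params(ft0$model), p_before)
  expect_identical(ft0$before$accuracy, ft0$after$accuracy)
  # labels outside the model's class set are rejected
  alien <- ds
  alien$labels[1] <- "juggling"
  expect_error(fine_tune(m, alien), "unseen class")
})

test_that("checkpoints round-trip through the key-value container", {
  ds <- separable_dataset(5)
  for (arch in c("cnn_lstm", "resnet")) {
    m <- train(build_architecture(spec_for(ds, arch)), ds, 2, lr = 1e-3)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    pa <- harkit:::.model_params(m); pb <- harkit:::.model_params(m2)
    expect_identical(names(pa), names(pb))
    for (nm in names(pa)) expect_equal(pb[[nm]], pa[[nm]], tolerance = 1e-12)
    w <- ds$X[2, , ]
    expect_equal(classify_window(m2, w)$probabilities,
                 classify_window(m, w)$probabilities, tolerance = 1e-9)
  }
})
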