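test_that("the default architecture matches the protocol", {
  arch <- cnn_architecture()
  expect_equal(arch$conv_filters, c(32L, 64L, 128L, 256L))
  expect_equal(arch$fc1_width, 280L)
  expect_equal(arch$dropout_rate, 0.5)
  expect_equal(arch$n_classes, 14L)
  expect_equal(arch$kernel, c(3L, 3L))
  expect_equal(arch$pool, c(2L, 2L))
})

test_that("inputs too small for four poolings are rejected", {
  expect_error(build_model(cnn_architecture(), c(8L, 400L)), "small")
  expect_silent(m <- build_model(cnn_architecture(), c(16L, 16L)))
})

test_that("parameter count matches the layer-by-layer arithmetic", {
  # input 64x400: conv stacks (3*3*cin+1+2)*cout, then 4x25x256 flatten
  # into 280 units, then 14 outputs; total derived by hand from the layer
  # formula before the model was built
  m <- build_model(cnn_architecture(), c(64L, 400L), seed = 2)
  expect_equal(n_params(m), 7561014L)
})

test_that("forward pass yields one probability simplex per record", {
  arch <- tiny_arch(n_classes = 4L)
  m <- build_model(arch, c(8L, 8L), seed = 1)
  p <- predict_proba(m, tiny_features(6, seed = 2))
  expect_equal(dim(p), c(6L, 4L))
  expect_true(all(is.finite(p)) && all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  # default model emits 14 scores
  m14 <- build_model(cnn_architecture(), c(16L, 16L), seed = 1)
  p14 <- predict_proba(m14, tiny_features(1, seed = 3, shape = c(16L, 16L)))
  expect_equal(ncol(p14), 14L)
})

test_that("analytic gradients agree with finite differences", {
  arch <- tiny_arch(n_classes = 3L)
  m <- build_model(arch, c(8L, 8L), seed = 3)
  feats <- tiny_features(4, seed = 4)
  X <- hearscene:::stack_features(feats)
  y <- c(1L, 2L, 3L, 1L)
  dims <- hearscene:::model_dims(m)
  out <- hearscene:::cnn_pass(m$params, m$running, X, y, dims, NULL,
                              TRUE, 0.9, TRUE)
  eps <- 1e-6
  set.seed(5)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      lp <- hearscene:::cnn_pass(pp, m$running, X, y, dims, NULL,
                                 TRUE, 0.9, FALSE)$loss
      lm <- hearscene:::cnn_pass(pm, m$running, X, y, dims, NULL,
                                 TRUE, 0.9, FALSE)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- out$grads[[nm]][i]
      if (abs(fd) + abs(an) < 1e-7) {
        succeed()                      # flat direction (e.g. conv bias
      } else {                         # cancelled by batchnorm)
        expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-5)
      }
    }
  }
})

test_that("training is reproducible given identical seeds and data", {
  arch <- tiny_arch(n_classes = 3L, dropout = 0.5)
  feats <- tiny_features(12, seed = 6)
  labs <- factor(rep(c("a", "b", "c"), 4))
  cfg <- training_config(max_epochs = 4L, patience = 3L, batch_size = 4L,
                         seed = 11)
  m1 <- train_classifier(build_model(arch, c(8L, 8L), seed = 2),
                         feats, labs, cfg)
  m2 <- train_classifier(build_model(arch, c(8L, 8L), seed = 2),
                         feats, labs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(predict_label(m1, feats), predict_label(m2, feats))
})

test_that("early stopping fires after patience epochs without improvement", {
  # zero learning rate and no dropout freeze the model, and a single
  # mini-batch per epoch makes the monitored loss exactly constant: the
  # run must stop after patience + 1 epochs
  arch <- tiny_arch(n_classes = 3L, dropout = 0)
  feats <- tiny_features(9, seed = 8)
  labs <- factor(rep(c("a", "b", "c"), 3))
  cfg <- training_config(learning_rate = 0, batch_size = 9L,
                         max_epochs = 40L, patience = 10L, seed = 4)
  m <- train_classifier(build_model(arch, c(8L, 8L), seed = 1),
                        feats, labs, cfg)
  expect_equal(m$epochs_run, 11L)
  expect_lt(diff(range(m$loss_history)), 1e-12)
})

test_that("training runs to max_epochs while the loss keeps improving", {
  arch <- tiny_arch(n_classes = 3L, dropout = 0)
  feats <- tiny_features(9, seed = 9)
  labs <- factor(rep(c("a", "b", "c"), 3))
  cfg <- training_config(max_epochs = 6L, patience = 5L, batch_size = 9L,
                         seed = 13)
  m <- train_classifier(build_model(arch, c(8L, 8L), seed = 5),
                        feats, labs, cfg)
  expect_lte(m$epochs_run, 6L)
  expect_gte(m$epochs_run, cfg$patience + 1L)
  if (all(diff(m$loss_history) < 0)) expect_equal(m$epochs_run, 6L)
})
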