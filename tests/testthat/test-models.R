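test_that("BPNN parameter count matches the closed-form architecture total", {
  model <- build_bpnn()
  closed_form <- (1814 * 512 + 512) + (512 * 128 + 128) +
    (128 * 16 + 16) + (16 * 4 + 4)
  expect_equal(count_parameters(model, input_dim = 1814), closed_form)
  expect_error(bpnn_config(hidden = c(512, -1)), "positive")
  expect_error(bpnn_config(lr = 0), "lr")
})

test_that("the AlexNet variant has no pooling and BN after the first three convs", {
  layers <- alexnet1d_layers()
  expect_false(any(grepl("pool", layers$type)))
  conv_rows <- which(layers$type == "conv1d")
  expect_length(conv_rows, 5)
  bn_follows <- layers$type[conv_rows + 1] == "batch_norm"
  expect_identical(bn_follows, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # every convolution is followed by ReLU (after BN where present)
  relu_after <- vapply(conv_rows, function(r) {
    any(layers$type[r + 1:2] == "relu")
  }, logical(1))
  expect_true(all(relu_after))
  expect_error(alexnet1d_config(channels = c(0, 2), kernels = c(3, 3),
                                strides = c(1, 1), bn = c(TRUE, FALSE)),
               "positive")
})

test_that("model gradients agree with finite differences", {
  set.seed(14)
  # BPNN with L2
  cfg <- teaorigin:::bpnn_config(hidden = c(5, 4, 3), l2 = 1e-3,
                                 n_class = 3)
  params <- teaorigin:::bpnn_init_params(cfg, 6)
  x <- matrix(rnorm(4 * 6), 4)
  y <- factor(c("a", "b", "c", "a"), levels = c("a", "b", "c"))
  fwd <- teaorigin:::bpnn_forward(params, x)
  gr <- teaorigin:::bpnn_backward(params, fwd, y, cfg$l2)
  lossf <- function(p) teaorigin:::bpnn_loss(p, x, y, cfg$l2)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      expect_equal(gr[[nm]][i], finite_diff(lossf, params, nm, i),
                   tolerance = 1e-5)
    }
  }
  # conv stack with batch normalization
  acfg <- alexnet1d_config(channels = c(3, 4), kernels = c(5, 3),
                           strides = c(2, 1), bn = c(TRUE, FALSE),
                           classifier = 6, n_class = 3)
  ap <- teaorigin:::alexnet_init_params(acfg, 20)
  xa <- matrix(rnorm(4 * 20), 4)
  fwd <- teaorigin:::alexnet_forward(ap, acfg, xa, train = TRUE)
  gr <- teaorigin:::alexnet_backward(ap, acfg, fwd, y)
  lossa <- function(p) {
    f <- teaorigin:::alexnet_forward(p, acfg, xa, train = TRUE)
    teaorigin:::cross_entropy(teaorigin:::softmax_rows(f$logits), y)
  }
  for (nm in names(ap)) {
    idx <- sample(length(ap[[nm]]), min(4, length(ap[[nm]])))
    for (i in idx) {
      expect_equal(gr[[nm]][i], lossa_fd <- finite_diff(lossa, ap, nm, i),
                   tolerance = 1e-4)
    }
  }
})

test_that("repset forward output is a permutation-invariant probability vector", {
  set.seed(31)
  cfg <- repset_config(m = 3, c = 2, window = 4, fc = 5, n_class = 4)
  params <- teaorigin:::repset_init_params(cfg)
  X <- matrix(rnorm(20), 5, 4)
  p <- repset_forward(X, params)
  expect_length(p, 4)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(repset_forward(X[sample(5), ], params), p)
  # zero features and zero biases give the uniform distribution
  zero_params <- params
  zero_params$H <- params$H * 0
  attr(zero_params$H, "m") <- cfg$m; attr(zero_params$H, "c") <- cfg$c
  zero_params$b1 <- zero_params$b1 * 0
  zero_params$b2 <- zero_params$b2 * 0
  expect_equal(repset_forward(X, zero_params), rep(0.25, 4))
})

test_that("the matching-layer gradient matches finite differences under a frozen assignment", {
  set.seed(40)
  cfg <- repset_config(m = 2, c = 2, window = 4, fc = 3, n_class = 2)
  params <- teaorigin:::repset_init_params(cfg)
  Xb <- rbind(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4))
  y <- factor(c("a", "b"), levels = c("a", "b"))
  pass <- teaorigin:::repset_batch_pass(params, Xb, 3,
                                        keep_assignment = TRUE)
  bn <- teaorigin:::repset_bn_forward(params, pass$feats)
  head <- teaorigin:::repset_head_forward(params, bn$out)
  gr <- teaorigin:::repset_backward(params, Xb, 3, y, pass, bn, head)
  lossf <- function(p) teaorigin:::repset_frozen_loss(p, Xb, 3, y, pass)
  for (i in seq_len(length(params$H))) {
    fd <- finite_diff(lossf, params, "H", i)
    expect_equal(gr$H[i], fd, tolerance = 1e-4)
  }
})

test_that("training is deterministic and learns separable synthetic data", {
  prep <- preprocess(generate_dataset(clean_config(n_per_class = 8)),
                     val_per_class = 1, seed = 3)
  x <- prep$dataset$absorbance
  y <- prep$dataset$label
  sp <- prep$split
  cfg <- bpnn_config(hidden = c(32, 16, 8), epochs = 40)
  m1 <- train_model(build_bpnn(cfg), x[sp$train, ], y[sp$train],
                    x[sp$validation, ], y[sp$validation], seed = 5)
  m2 <- train_model(build_bpnn(cfg), x[sp$train, ], y[sp$train],
                    x[sp$validation, ], y[sp$validation], seed = 5)
  expect_identical(m1$log, m2$log)
  expect_equal(nrow(m1$log), cfg$epochs)
  # noise-free, well-separated classes are learned to 100% on train
  train_acc <- mean(predict(m1, x[sp$train, ]) == y[sp$train])
  expect_equal(train_acc, 1)
  # and clearly above chance on test
  expect_gt(mean(predict(m1, x[sp$test, ]) == y[sp$test]), 0.25)
  expect_error(train_model(build_bpnn(cfg), x[0, , drop = FALSE],
                           y[0]), "non-empty")
})

test_that("prediction breaks probability ties toward the lowest class index", {
  prob <- matrix(0.25, 3, 4)
  lab <- teaorigin:::argmax_labels(prob, maojian_classes())
  expect_true(all(lab == "Changsha"))
  # single-sample prediction yields a single label
  prep <- preprocess(generate_dataset(clean_config(n_per_class = 4,
                                                   n_points = 200)),
                     val_per_class = 0, seed = 1)
  cfg <- repset_config(m = 4, c = 3, window = 50, fc = 8, epochs = 2)
  m <- train_model(build_repset(cfg), prep$dataset$absorbance,
                   prep$dataset$label, seed = 2)
  p <- predict(m, prep$dataset$absorbance[1, , drop = FALSE])
  expect_length(p, 1)
})

test_that("the hidden-set sweep returns the accuracy grid and best cell", {
  prep <- preprocess(generate_dataset(clean_config(n_per_class = 6,
                                                   n_points = 200)),
                     val_per_class = 1, seed = 4)
  cfg <- repset_config(window = 50, fc = 8, epochs = 4)
  sw <- sweep_hidden_sets(c(3, 6), 3, prep$dataset, prep$split,
                          seed = 5, config = cfg)
  expect_equal(dim(sw$accuracy), c(2, 1))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_true(sw$best[["accuracy"]] == max(sw$accuracy))
  sw1 <- sweep_hidden_sets(4, 2, prep$dataset, prep$split, seed = 5,
                           config = cfg)
  expect_equal(dim(sw1$accuracy), c(1, 1))
  expect_error(sweep_hidden_sets(integer(0), 3, prep$dataset, prep$split),
               "non-empty")
})
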