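tiny_rho_bundle <- function(n = 160, T = 8, d = 6, seed = 1) {
  # synthetic recurrent-task bundle: label is recoverable from the inputs
  set.seed(seed)
  mk <- function(k, shift = 0) {
    x <- array(rnorm(k * T * d), c(k, T, d)) + shift
    y <- 2 + rowMeans(x[, , 1]) # depends on channel 1
    list(x = list(x = x, mask = matrix(1, k, T)), y = y)
  }
  src_tr <- mk(n); src_val <- mk(40); src_te <- mk(40)
  tgt_tr <- mk(n, shift = 0); tgt_val <- mk(40)
  dataset_bundle(
    source = list(train = src_tr, val = src_val, test = src_te),
    target = list(train_x = tgt_tr$x, val_x = tgt_val$x,
                  test = list(x = tgt_tr$x, y = tgt_tr$y),
                  hidden_y = tgt_tr$y, hidden_val_y = tgt_val$y),
    meta = list(task = "rho_regression", scenario = "toy", max_sites = T))
}

test_that("one epoch of minibatches uses each source example exactly once", {
  set.seed(8)
  cfg <- training_config(batch_size = 64)
  batches <- make_minibatches(n_source = 250, n_target = 80, cfg)
  ls <- unlist(lapply(batches, `[[`, "labeled_source"))
  expect_identical(sort(ls), 1:250)
  # domain mixture: 32 + 32 at batch size 64 with the default fraction
  expect_identical(length(batches[[1]]$domain_source), 32L)
  expect_identical(length(batches[[1]]$domain_target), 32L)
  # the domain-source component reuses the same pool, shuffled differently
  ds <- unlist(lapply(batches, `[[`, "domain_source"))
  expect_true(all(ds %in% 1:250))
  expect_false(identical(ds[1:64], ls[1:64]))
  # target indices cycle through the smaller pool
  dt <- unlist(lapply(batches, `[[`, "domain_target"))
  expect_true(all(sort(unique(dt)) == 1:80))
  expect_error(make_minibatches(100, 0, cfg), "configuration error")
})

test_that("lambda = 0 training matches the standard trajectory exactly", {
  b <- tiny_rho_bundle()
  spec <- network_spec("rho_regression", input_shape = c(8, 6), hidden = 6,
                       feature_dim = 6)
  cfg <- training_config(batch_size = 32, max_epochs = 4, patience = 10,
                         seed = 7)
  set.seed(11)
  m_std <- build_network(spec)
  fit_std <- train_standard(m_std, b$source, cfg)
  set.seed(11)
  m_da <- build_network(spec)
  cfg0 <- cfg
  cfg0$lambda <- 0
  fit_da <- train_domain_adaptive(m_da, b, cfg0)
  # identical seeds and zero reversal weight: identical label-path training
  expect_equal(fit_da$history$label_val, fit_std$history$label_val,
               tolerance = 1e-12)
  p1 <- predict(m_std, b$source$test$x)
  p2 <- predict(m_da, b$source$test$x)
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-12)
})

test_that("the combined update equals label gradient minus lambda times domain gradient", {
  # accumulate the two components separately on a toy network and compare
  # against the joint backward pass used in training
  set.seed(9)
  spec <- network_spec("rho_regression", input_shape = c(5, 4), hidden = 4,
                       feature_dim = 4, lambda = 1.5)
  m <- build_network(spec, seed = 10)
  xb <- list(x = array(rnorm(6 * 5 * 4), c(6, 5, 4)), mask = matrix(1, 6, 5))
  yb <- rnorm(6)
  dlab <- rep(0:1, each = 3)
  layers <- popdann:::all_layers(m)
  # joint pass
  popdann:::zero_grads(layers)
  feat <- popdann:::stack_forward(m$feature, xb)
  out <- popdann:::stack_forward(m$label_head, feat)
  ls <- popdann:::mse_loss(out, yb)
  popdann:::stack_backward(m$feature, popdann:::stack_backward(m$label_head, ls$grad))
  outd <- popdann:::stack_forward(m$domain_head, feat)
  lsd <- popdann:::xent_loss(outd, dlab)
  popdann:::stack_backward(m$feature, popdann:::stack_backward(m$domain_head, lsd$grad))
  joint <- lapply(m$feature, function(l) l$grads)
  # separate passes
  popdann:::zero_grads(layers)
  feat <- popdann:::stack_forward(m$feature, xb)
  out <- popdann:::stack_forward(m$label_head, feat)
  ls <- popdann:::mse_loss(out, yb)
  popdann:::stack_backward(m$feature, popdann:::stack_backward(m$label_head, ls$grad))
  g_label <- lapply(m$feature, function(l) l$grads)
  popdann:::zero_grads(layers)
  feat <- popdann:::stack_forward(m$feature, xb)
  outd <- popdann:::stack_forward(m$domain_head, feat)
  lsd <- popdann:::xent_loss(outd, dlab)
  # bypass the GRL to measure the un-reversed domain gradient
  d_nogrl <- popdann:::stack_backward(m$domain_head[-1], lsd$grad)
  popdann:::stack_backward(m$feature, d_nogrl)
  g_domain <- lapply(m$feature, function(l) l$grads)
  for (i in seq_along(joint)) {
    for (nm in names(joint[[i]])) {
      expect_equal(joint[[i]][[nm]],
                   g_label[[i]][[nm]] - 1.5 * g_domain[[i]][[nm]],
                   tolerance = 1e-10)
    }
  }
})

test_that("early stopping restores the label-loss optimum and training is seeded", {
  b <- tiny_rho_bundle()
  spec <- network_spec("rho_regression", input_shape = c(8, 6), hidden = 6,
                       feature_dim = 6)
  cfg <- training_config(batch_size = 32, max_epochs = 12, patience = 3,
                         lr = 5e-3, seed = 21)
  set.seed(2); m1 <- build_network(spec)
  f1 <- train_standard(m1, b$source, cfg)
  expect_equal(f1$history$label_val[f1$best_epoch], min(f1$history$label_val))
  set.seed(2); m2 <- build_network(spec)
  f2 <- train_standard(m2, b$source, cfg)
  expect_identical(f1$history, f2$history)
  # the toy label is learnable: validation loss improves over the start
  expect_lt(min(f1$history$label_val), f1$history$label_val[1])
})

test_that("domain-adaptive training requires target data and finite losses", {
  b <- tiny_rho_bundle()
  b$target$train_x <- NULL
  spec <- network_spec("rho_regression", input_shape = c(8, 6), hidden = 4,
                       feature_dim = 4)
  m <- build_network(spec, seed = 1)
  expect_error(train_domain_adaptive(m, b, training_config()),
               "configuration error")
})
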