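# finite-difference oracle used for the gradient contracts
fd_grad <- function(layers, x, eps = 1e-5) {
  loss <- function() sum(stack_forward_t(layers, x)^2)
  out <- stack_forward_t(layers, x)
  popdann:::zero_grads(layers)
  popdann:::stack_backward(layers, 2 * out)
  checks <- c()
  for (l in layers) for (nm in names(l$params)) {
    P <- l$params[[nm]]
    for (k in sample(length(P), min(6, length(P)))) {
      l$params[[nm]][k] <- P[k] + eps
      lp <- loss()
      l$params[[nm]][k] <- P[k] - eps
      lm <- loss()
      l$params[[nm]][k] <- P[k]
      num <- (lp - lm) / (2 * eps)
      ana <- l$grads[[nm]][k]
      checks <- c(checks, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  max(checks)
}
stack_forward_t <- function(layers, x) popdann:::stack_forward(layers, x)

test_that("gradient reversal is the identity forward and negation backward", {
  set.seed(1)
  x <- matrix(rnorm(12), 3, 4)
  expect_identical(gradient_reversal(x, 2), x)
  # toy network: feature extractor + (GRL -> head); feature gradients under
  # the downstream loss equal -lambda times those with the reversal removed
  for (lambda in c(0.5, 1, 2)) {
    feat <- list(popdann:::nn_dense(4, 3, "tanh"))
    head <- list(popdann:::nn_grl(lambda), popdann:::nn_dense(3, 2, "linear"))
    f <- popdann:::stack_forward(feat, x)
    out <- popdann:::stack_backward
    y <- popdann:::stack_forward(head, f)
    popdann:::zero_grads(c(feat, head))
    d_with <- popdann:::stack_backward(head, 2 * y)
    popdann:::zero_grads(head[2])
    y2 <- popdann:::stack_forward(head[2], f)
    d_without <- popdann:::stack_backward(head[2], 2 * y2)
    expect_lt(max(abs(d_with + lambda * d_without)), 1e-12)
  }
})

test_that("all layer backward passes match finite differences", {
  set.seed(42)
  dense <- list(popdann:::nn_dense(5, 7, "tanh"),
                popdann:::nn_dense(7, 3, "relu"),
                popdann:::nn_dense(3, 2, "linear"))
  expect_lt(fd_grad(dense, matrix(rnorm(20), 4, 5)), 1e-6)
  gru <- list(popdann:::nn_gru(6, 5, use_last = TRUE),
              popdann:::nn_dense(10, 2, "linear"))
  xg <- list(x = array(rnorm(3 * 8 * 6), c(3, 8, 6)),
             mask = matrix(c(rep(1, 20), rep(0, 4)), 3, 8))
  expect_lt(fd_grad(gru, xg), 1e-6)
  grs <- list(popdann:::nn_gru(6, 5, summaries = TRUE),
              popdann:::nn_dense(12, 2, "linear"))
  expect_lt(fd_grad(grs, xg), 1e-6)
  conv <- list(popdann:::nn_conv2d(3, 4), popdann:::nn_meanpool2(),
               popdann:::nn_conv2d(4, 5), popdann:::nn_gpool(),
               popdann:::nn_dense(5, 2, "linear"))
  expect_lt(fd_grad(conv, array(rnorm(2 * 11 * 11 * 3), c(2, 11, 11, 3))), 1e-6)
})

test_that("build_network wires the three components per task", {
  spec <- network_spec("sweep_classification", input_shape = c(15, 15, 3))
  m <- build_network(spec, seed = 1)
  expect_named(count_parameters(m), c("feature", "label", "domain", "total"))
  expect_gt(count_parameters(m)$total, 0)
  x <- array(rnorm(4 * 15 * 15 * 3), c(4, 15, 15, 3))
  p <- predict(m, x)
  expect_equal(p$P_neu + p$P_sweep, rep(1, 4), tolerance = 1e-6)
  d <- predict(m, x, type = "domain")
  expect_true(all(d >= 0))
  expect_equal(d$P_source + d$P_target, rep(1, 4), tolerance = 1e-6)
  # deterministic inference
  expect_identical(predict(m, x), predict(m, x))
  expect_error(build_network(network_spec("sweep_classification",
                                          input_shape = c(4, 4, 3))),
               "construction error")
  expect_error(build_network(network_spec("rho_regression",
                                          input_shape = c(10, 10, 3))),
               "construction error")
})

test_that("a regression model fits a constant-label dataset", {
  set.seed(3)
  x <- list(x = array(rnorm(120 * 10 * 6), c(120, 10, 6)),
            mask = matrix(1, 120, 10))
  y <- rep(2.5, 120)
  spec <- network_spec("rho_regression", input_shape = c(10, 6), hidden = 8,
                       feature_dim = 8)
  m <- build_network(spec, seed = 4)
  cfg <- training_config(batch_size = 32, max_epochs = 30, patience = 30,
                         lr = 1e-2, seed = 5)
  fit <- train_standard(m, list(train = list(x = x, y = y),
                                val = list(x = popdann:::slice_x(x, 1:20),
                                           y = y[1:20])), cfg)
  pred <- predict(m, popdann:::slice_x(x, 1:50))$estimate * 1e8
  expect_lt(mae(y[1:50], pred) / 2.5, 0.05)
})

test_that("detaching the domain branch leaves label outputs identical", {
  spec <- network_spec("rho_regression", input_shape = c(8, 6))
  m <- build_network(spec, seed = 2)
  x <- list(x = array(rnorm(3 * 8 * 6), c(3, 8, 6)), mask = matrix(1, 3, 8))
  before <- predict(m, x)
  m$domain_head <- NULL  # detach
  expect_identical(predict(m, x), before)
})
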