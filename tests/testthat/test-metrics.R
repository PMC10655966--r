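test_that("AUPRC handles the canonical cases", {
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)  # perfect
  expect_error(auprc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "single class")
  # random scores on balanced labels hover near the positive fraction
  set.seed(1)
  vals <- replicate(50, auprc(rep(c(0, 1), 50), stats::runif(100)))
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("metric implementations agree with independent references", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- stats::rnorm(n)
    expect_equal(auprc(labels, scores), oracle_auprc(labels, scores),
                 tolerance = 1e-10)
    a <- stats::rnorm(sample(5:30, 1))
    b <- stats::rnorm(sample(5:30, 1), mean = stats::runif(1, -1, 1))
    w <- welch_t(a, b)
    ref <- stats::t.test(a, b)  # Welch by default
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    truth <- stats::rnorm(n)
    pred <- truth + stats::rnorm(n, 0.3, 0.5)
    expect_equal(mae(truth, pred), mean(abs(pred - truth)))
    expect_equal(rmse(truth, pred), sqrt(mean((pred - truth)^2)))
    expect_equal(bias(truth, pred), mean(pred - truth))
    expect_gte(rmse(truth, pred), abs(bias(truth, pred)))
  }
})

test_that("welch_t is zero for identical samples", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("ties in scores are integrated as one threshold group", {
  labels <- c(1, 0, 1, 0)
  scores <- c(0.7, 0.7, 0.4, 0.2)
  expect_equal(auprc(labels, scores), oracle_auprc(labels, scores))
})
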