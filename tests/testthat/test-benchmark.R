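tiny_cfg <- function(scenarios, seeds = 1L) {
  pair <- scenario_tree_inference_only(n_samples = 8L, L = 5e3)
  experiment_config(
    pair, n_source = 80L,
    scenarios = scenarios,
    training = training_config(batch_size = 32, max_epochs = 2, patience = 2),
    network = network_spec("sweep_classification", input_shape = c(7, 7, 3),
                           conv_channels = 4L, feature_dim = 8L),
    replicate_seeds = seeds,
    splits = c(train = 0.7, val = 0.1, test = 0.2))
}

test_that("a single-scenario request yields exactly that scenario", {
  rep <- run_benchmark(tiny_cfg("source_matched"))
  expect_s3_class(rep, "benchmark_report")
  expect_named(rep$replicates[["1"]]$metrics, "source_matched")
  tab <- benchmark_summary(rep)
  expect_identical(nrow(tab), 1L)
  expect_true(tab$auprc >= 0 && tab$auprc <= 1)
})

test_that("the four scenarios share the target test set and reports persist", {
  cfg <- tiny_cfg(c("source_matched", "target_matched", "standard",
                    "domain_adaptive"))
  rep <- run_benchmark(cfg)
  m <- rep$replicates[["1"]]$metrics
  expect_named(m, c("source_matched", "target_matched", "standard",
                    "domain_adaptive"))
  # target-facing scenarios are evaluated on identical truths
  expect_identical(m$standard$predictions$truth,
                   m$domain_adaptive$predictions$truth)
  expect_identical(m$target_matched$predictions$truth,
                   m$standard$predictions$truth)
  d <- file.path(tempdir(), "benchrep")
  write_benchmark_report(rep, d)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
  expect_true(file.exists(file.path(d, "predictions.tsv")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(js$task, "sweep_classification")
  preds <- utils::read.table(file.path(d, "predictions.tsv"), header = TRUE,
                             sep = "\t")
  expect_setequal(unique(preds$scenario), names(m))
  unlink(d, recursive = TRUE)
})

test_that("benchmark reports are reproducible from (config, seed)", {
  cfg <- tiny_cfg("standard")
  t1 <- benchmark_summary(run_benchmark(cfg))
  t2 <- benchmark_summary(run_benchmark(cfg))
  expect_identical(t1, t2)
})

test_that("suite runners validate their presets and arguments", {
  cfg <- tiny_cfg("standard")
  expect_error(run_misspec_suite(cfg, degrees = "bottleneck_42"),
               "configuration error")
  expect_error(run_imbalance_suite(cfg, sweep_fractions = 1.4), "sweep_fractions")
  expect_error(run_imbalance_suite(cfg, ratios = 0.5), "ratios")
})

test_that("the imbalance suite evaluates on a balanced test set", {
  cfg <- tiny_cfg(c("standard", "domain_adaptive"))
  res <- run_imbalance_suite(cfg, sweep_fractions = 0.8, ratios = 1)
  tab <- attr(res, "summary")
  expect_identical(unique(tab$sweep_fraction), 0.8)
  rep <- res[[1]]
  truth <- rep$replicates[["1"]]$metrics$standard$predictions$truth
  expect_equal(mean(truth), 0.5, tolerance = 0.26)
})
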