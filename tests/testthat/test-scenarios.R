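test_that("scenario presets encode their mis-specification", {
  p <- scenario_tree_inference_only()
  expect_identical(p$task, "sweep_classification")
  expect_null(p$source$inference_error)
  expect_equal(p$target$inference_error$p_nni, 0.05)
  pb <- scenario_bottleneck(500)
  expect_equal(ne_at(pb$target$demography, 1500), 500)
  expect_equal(ne_at(pb$target$demography, 500), 1e4)
  expect_equal(ne_at(pb$source$demography, 1500), 1e4)
  px <- scenario_extreme()
  expect_equal(px$target$rho, 1e-7)              # 8-fold mis-specified rho
  expect_equal(px$source$rho, 1.25e-8)
  expect_s3_class(px$target$bgs, "bgs_config")
  pr <- scenario_relernn_demography()
  expect_identical(pr$task, "rho_regression")
  expect_equal(pr$L, 3e5)
  expect_equal(pr$target$mu_range, c(1.875e-8, 3.125e-8))
  expect_equal(pr$target$rho_range, c(0, 6.25e-8))
  nm <- scenario_no_misspec()
  expect_identical(nm$source$demography$ne, nm$target$demography$ne)
})

test_that("dataset assembly honors splits, mixtures and label stripping", {
  set.seed(1)
  pair <- scenario_no_misspec("rho_regression", n_samples = 8L, L = 4e3)
  b <- assemble_dataset(pair, n_source = 60, n_target = 50,
                        splits = c(train = 0.7, val = 0.1, test = 0.2),
                        seed = 3)
  expect_s3_class(b, "dataset_bundle")
  expect_equal(popdann:::n_examples(b$source$train$x), 42)
  expect_equal(popdann:::n_examples(b$source$val$x), 6)
  expect_equal(popdann:::n_examples(b$source$test$x), 12)
  # unlabeled target portions expose no labels; the held-out test does
  expect_null(b$target$train_y)
  expect_length(b$target$test$y, 10)
  expect_true(all(b$target$test$y >= 0 & b$target$test$y <= 6.25))
  # deterministic under the seed
  set.seed(99)
  b2 <- assemble_dataset(pair, n_source = 60, n_target = 50,
                         splits = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 3)
  expect_equal(b$source$train$x$x, b2$source$train$x$x)
  expect_error(assemble_dataset(pair, n_source = 60, n_target = 5, seed = 1),
               "size error")
})

test_that("class mixtures and domain-size ratios are respected", {
  set.seed(2)
  pair <- scenario_tree_inference_only(n_samples = 8L, L = 5e3)
  b <- assemble_dataset(pair, n_source = 40, target_sweep_fraction = 1,
                        source_target_ratio = 2,
                        splits = c(train = 0.6, val = 0.1, test = 0.3),
                        seed = 4)
  expect_equal(b$meta$n_target, 20)
  # adversarial all-sweep unlabeled target
  expect_true(all(b$target$hidden_y == 1))
  # source stays balanced
  expect_equal(mean(b$source$train$y), 0.5, tolerance = 0.2)
  # encodings are lower-triangular tensors of the right shape
  expect_identical(dim(b$source$train$x)[2:4], c(7L, 7L, 3L))
})

test_that("genotype packing pads, masks and truncates correctly", {
  ex <- list(
    list(genotypes = matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L), 2, 4),
         positions = c(100, 900), mu = 2e-8, rho = 3e-8, n_sites = 2L),
    list(genotypes = matrix(integer(0), 0, 4), positions = numeric(0),
         mu = 2e-8, rho = 0, n_sites = 0L))
  p <- pack_genotype_examples(ex, L = 1000, max_sites = 3)
  expect_identical(dim(p$x), c(2L, 3L, 7L))
  expect_equal(p$mask[1, ], c(1, 1, 0))
  expect_equal(p$mask[2, ], c(0, 0, 0))    # zero-site example kept, flagged
  expect_equal(p$x[1, 1, 1:4], c(1, -1, 1, -1))
  expect_equal(p$x[1, 2, 5], 0.9)                 # normalized position
  expect_equal(p$x[1, 2, 6], 50 * 0.8)            # scaled inter-site gap
  expect_equal(p$rho, c(3e-8, 0))
  # truncation keeps an evenly spaced subset
  ex3 <- list(list(genotypes = matrix(1L, 10, 4) * (diag(10) %*% matrix(1L, 10, 4) > 0),
                   positions = seq(50, 950, length.out = 10), mu = 2e-8,
                   rho = 1e-8, n_sites = 10L))
  p3 <- pack_genotype_examples(ex3, L = 1000, max_sites = 4)
  expect_equal(sum(p3$mask[1, ]), 4)
})

test_that("Watterson calibration recovers the equilibrium Ne of the target", {
  pair <- scenario_no_misspec("rho_regression", n_samples = 16L, L = 2e4)
  ne <- calibrate_source_ne(pair, n_regions = 60, seed = 2)
  expect_lt(abs(ne - 1e4) / 1e4, 0.2)
})
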