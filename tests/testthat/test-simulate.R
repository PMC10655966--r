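test_that("Watterson's estimator and the implied Ne follow the closed forms", {
  expect_equal(watterson_theta(0, 10, 1000), 0)
  expect_equal(watterson_theta(6, 4, 1), 6 / (1 + 1 / 2 + 1 / 3))
  expect_error(watterson_theta(5, 1, 100), "domain error")
  expect_equal(equilibrium_ne(5e-4, 1.25e-8), 10000)
  expect_equal(equilibrium_ne(0, 1e-8), 0)
  expect_error(equilibrium_ne(1e-3, 0), "domain error")
  # paper-scale check: theta_W / (4 mu) at mu = 2.5e-8 for a 300 kb region
  expect_equal(equilibrium_ne(watterson_theta(2921, 32, 3e5), 2.5e-8),
               2921 / (sum(1 / (1:31)) * 3e5 * 4 * 2.5e-8))
})

test_that("neutral equilibrium diversity matches 4 Ne mu", {
  set.seed(91)
  dem <- eq_demog(1e4)
  pis <- replicate(100, {
    r <- simulate_region(dem, L = 2e4, mu = 1.25e-8, rho = 1.25e-8,
                         n_samples = 16)
    if (r$n_sites == 0) return(0)
    f <- rowMeans(r$genotypes)
    sum(2 * f * (1 - f) * 16 / 15) / r$L
  })
  exp_pi <- 4 * 1e4 * 1.25e-8
  z <- (mean(pis) - exp_pi) / (stats::sd(pis) / sqrt(length(pis)))
  expect_lt(abs(z), 4)
})

test_that("rho = 0 gives a single marginal tree and seeds reproduce exactly", {
  dem <- eq_demog()
  r0 <- simulate_region(dem, L = 5e4, mu = 1.25e-8, rho = 0, n_samples = 8,
                        seed = 4)
  expect_identical(length(r0$trees), 1L)
  r1 <- simulate_region(dem, L = 5e4, mu = 1.25e-8, rho = 1.25e-8,
                        n_samples = 8, seed = 42)
  r2 <- simulate_region(dem, L = 5e4, mu = 1.25e-8, rho = 1.25e-8,
                        n_samples = 8, seed = 42)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(r1$positions, r2$positions)
  # every marginal tree is a valid genealogy and intervals tile [0, L)
  for (tr in r1$trees) expect_silent(genealogy(tr$parent, tr$node_time))
  expect_equal(r1$intervals[1, 1], 0)
  expect_equal(r1$intervals[nrow(r1$intervals), 2], 5e4)
  if (nrow(r1$intervals) > 1) {
    expect_equal(r1$intervals[-1, 1], r1$intervals[-nrow(r1$intervals), 2])
  }
})

test_that("per-example mutation and recombination draws follow their ranges", {
  set.seed(5)
  dem <- eq_demog()
  ex <- replicate(300, simulate_relernn_example(dem, n = 8L, L = 5e3),
                  simplify = FALSE)
  rhos <- vapply(ex, function(e) e$rho, numeric(1))
  mus <- vapply(ex, function(e) e$mu, numeric(1))
  expect_true(all(rhos >= 0 & rhos <= 6.25e-8))
  expect_true(all(mus >= 1.875e-8 & mus <= 3.125e-8))
  expect_lt(abs(mean(rhos) - 3.125e-8) / 3.125e-8, 0.15)
  # segregating sites grow with the drawn mutation rate
  S <- vapply(ex, function(e) as.numeric(e$n_sites), numeric(1))
  expect_gt(stats::cor(mus, S, method = "spearman"), 0.1)
})

test_that("a hard sweep depresses diversity near the selected site", {
  set.seed(17)
  dem <- eq_demog(1e4)
  sw <- sweep_params(s = 0.01, condition = "frequency", freq = 0.9)
  pi_in <- numeric(60); pi_out <- numeric(60)
  for (i in 1:60) {
    r <- simulate_region(dem, L = 5e4, mu = 1.25e-8, rho = 1.25e-8,
                         n_samples = 16, sweep = sw)
    mid <- abs(r$positions - 2.5e4) < 5e3
    far <- r$positions < 5e3 | r$positions > 4.5e4
    pw <- function(sel) {
      if (!any(sel)) return(0)
      f <- rowMeans(r$genotypes[sel, , drop = FALSE])
      sum(2 * f * (1 - f) * 16 / 15)
    }
    pi_in[i] <- pw(mid) / 1e4
    pi_out[i] <- pw(far) / 1e4
  }
  expect_lt(mean(pi_in), mean(pi_out))
  expect_lt(stats::t.test(pi_in, pi_out, alternative = "less")$p.value, 0.05)
})

test_that("sweep genealogies carry a monophyletic derived set", {
  set.seed(23)
  dem <- eq_demog()
  for (i in 1:10) {
    g <- sweep_genealogy(24, dem, sweep_params(s = 0.01))
    expect_s3_class(g, "genealogy")
    nd <- length(g$derived_leaves)
    expect_gt(nd, 0)
    expect_lt(nd, 24)
    expect_silent(check_encoding_invariants(encode_genealogy(g)))
  }
})

test_that("the background-selection surrogate scales diversity by B", {
  cfg <- bgs_config(genic_span = c(45e3, 55e3), B = 0.8)
  dem <- eq_demog(1e4)
  out <- apply_bgs_surrogate(cfg, dem)
  expect_equal(out$B, 0.8)
  expect_equal(out$demography$ne, 8000)
  expect_error(apply_bgs_surrogate(bgs_config(c(0, 1), mode = "external"), dem),
               "configuration error")
  # B = 1 leaves the configuration unchanged
  same <- apply_bgs_surrogate(bgs_config(c(0, 1), B = 1), dem)
  expect_equal(same$demography$ne, dem$ne)
  # diversity scales accordingly (Watterson over replicates)
  set.seed(3)
  S1 <- replicate(60, simulate_region(dem, 2e4, 1.25e-8, 0, 12,
                                      genotypes = FALSE)$n_sites)
  S2 <- replicate(60, simulate_region(out$demography, 2e4, 1.25e-8, 0, 12,
                                      genotypes = FALSE)$n_sites)
  expect_lt(abs(mean(S2) / mean(S1) - 0.8), 0.12)
})

test_that("the inference-error surrogate honors its contracts", {
  set.seed(31)
  g <- with_random_focal(rand_tree(16))
  expect_identical(apply_inference_error(g, 0, 0), g)
  # branch noise alone preserves the tree topology (coalescence ranks may
  # reshuffle once times are perturbed)
  g2 <- apply_inference_error(g, sigma_bl = 0.4, p_nni = 0, seed = 9)
  expect_equal(suppressWarnings(
    ape::dist.topo(genealogy_to_phylo(g2), genealogy_to_phylo(g)))[1], 0)
  expect_false(isTRUE(all.equal(coalescent_times(g2), coalescent_times(g))))
  expect_silent(validate_genealogy(g2))
  # F-matrix distortion grows with the topology-move probability
  dist_for <- function(p_nni) {
    mean(replicate(40, {
      g0 <- with_random_focal(rand_tree(12))
      F0 <- encode_genealogy(g0, "F")$F
      F1 <- encode_genealogy(apply_inference_error(g0, 0.1, p_nni), "F")$F
      sqrt(sum((F1 - F0)^2))
    }))
  }
  d <- vapply(c(0, 0.1, 0.4), dist_for, numeric(1))
  expect_true(d[1] <= d[2] && d[2] < d[3])
})

test_that("extract_focal_genealogy respects half-open intervals and focal sites", {
  dem <- eq_demog()
  r <- simulate_region(dem, L = 1e5, mu = 1.25e-8, rho = 1.25e-8,
                       n_samples = 10, seed = 12)
  g <- extract_focal_genealogy(r, 5e4)
  expect_s3_class(g, "genealogy")
  idx <- which(r$intervals[, 1] <= 5e4 & 5e4 < r$intervals[, 2])
  expect_equal(sort(g$node_time), sort(r$trees[[idx]]$node_time))
  expect_error(extract_focal_genealogy(r, 2e5), "range error")
  expect_error(extract_focal_genealogy(r, 777.7, focal_site_required = TRUE),
               "data error")
  # a sweep region always carries its focal variant
  sw <- sweep_params(s = 0.01)
  rs <- simulate_region(dem, L = 2e4, mu = 1.25e-8, rho = 1.25e-8,
                        n_samples = 12, sweep = sw, seed = 3)
  gf <- extract_focal_genealogy(rs, rs$focal_position, focal_site_required = TRUE)
  expect_identical(gf$derived_leaves, rs$derived_leaves)
})

test_that("the packaged European demography yields the expected epochs", {
  dem <- european_demography()
  expect_s3_class(dem, "demography_model")
  expect_equal(dem$start_gen[1], 0)
  expect_gt(dem$ne[1], 4e5)                      # recent explosive growth
  expect_equal(dem$ne[length(dem$ne)], 7310)     # ancestral size
  expect_true(any(abs(dem$ne - 1861) < 1))      # out-of-Africa bottleneck
  expect_equal(ne_at(dem, 3000), 14474)
})
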