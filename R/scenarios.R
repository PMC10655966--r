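#' Matched source/target simulation scenario
#'
#' A `scenario_pair` holds the full simulation configuration of a source
#' domain (the "well-specified" simulations a model is trained on) and a
#' target domain (the same task with a chosen mis-specification: a
#' demographic bottleneck, background selection, a wrong recombination
#' rate, and/or genealogy-inference error). Source and target always share
#' the region length, sample size and task definition.
#'
#' @param task `"sweep_classification"`, `"s_regression"` or
#'   `"rho_regression"`.
#' @param source,target domain configurations (lists with `demography`,
#'   `mu`, `rho` or `mu_range`/`rho_range`, and optional `sweep_s_range`,
#'   `inference_error`, `bgs`, `rho_override`).
#' @param n_samples haploid sample size (shared).
#' @param L region length in bp (shared).
#' @param label free-text scenario name.
#' @return A `scenario_pair` object.
#' @export
scenario_pair <- function(task, source, target, n_samples, L, label = "") {
  stopifnot(task %in% c("sweep_classification", "s_regression", "rho_regression"))
  structure(list(task = task, source = source, target = target,
                 n_samples = as.integer(n_samples), L = L, label = label),
            class = "scenario_pair")
}

#' @export
print.scenario_pair <- function(x, ...) {
  cat(sprintf("<scenario_pair> %s | task = %s | n = %d, L = %g bp\n",
              if (nzchar(x$label)) x$label else "(unnamed)", x$task,
              x$n_samples, x$L))
  cat(sprintf("  source: %s\n  target: %s\n",
              x$source$demography$label, x$target$demography$label))
  invisible(x)
}

eq_domain <- function(ne = 1e4, mu = 1.25e-8, rho = 1.25e-8,
                      sweep_s_range = c(0.002, 0.01)) {
  list(demography = demography_model(0, ne, sprintf("equilibrium Ne = %g", ne)),
       mu = mu, rho = rho, sweep_s_range = sweep_s_range)
}

#' Scenario presets for the mis-specification experiments
#'
#' Constructors for the benchmark scenarios:
#'
#' * `scenario_tree_inference_only()`: source and target share the
#'   equilibrium demography (Ne = 10,000, mu = rho = 1.25e-8); the target
#'   consists of genealogies passed through the inference-error surrogate —
#'   mis-specification from tree inference alone.
#' * `scenario_bottleneck(ne_b)`: the target demography additionally drops
#'   to `ne_b` (8,000 / 5,000 / 2,000 / 500) between generations 1,000 and
#'   2,000 before the present.
#' * `scenario_extreme()`: the Ne = 500 bottleneck plus background
#'   selection plus an 8-fold mis-specified recombination rate (target
#'   rho = 1e-7 vs. source 1.25e-8).
#' * `scenario_relernn_bgs()`: recombination-rate task; the target carries
#'   the background-selection surrogate (constrained central 100 kb of a
#'   300 kb segment).
#' * `scenario_relernn_demography()`: recombination-rate task; the target
#'   follows the packaged European demography and the source is an
#'   equilibrium population whose Ne is calibrated from target data via
#'   Watterson's estimator (see [calibrate_source_ne()]).
#' * `scenario_no_misspec()`: source and target drawn from the identical
#'   distribution (the safety control).
#'
#' Genealogy-task targets always include the inference-error surrogate
#' (reconstructed trees are what a real application observes); its
#' parameters default to `sigma_bl = 0.3`, `p_nni = 0.05`.
#'
#' @param n_samples,L shared sample size and region length.
#' @param sigma_bl,p_nni inference-error surrogate parameters.
#' @param ne_b bottleneck effective size.
#' @param task task for `scenario_no_misspec`.
#' @param source_ne calibrated source Ne; `NULL` triggers on-the-fly
#'   calibration from pilot target simulations when the dataset is
#'   assembled.
#' @name scenario-presets
NULL

#' @rdname scenario-presets
#' @export
scenario_tree_inference_only <- function(n_samples = 32L, L = 1e5,
                                         sigma_bl = 0.3, p_nni = 0.05) {
  src <- eq_domain()
  tgt <- src
  tgt$inference_error <- list(sigma_bl = sigma_bl, p_nni = p_nni)
  scenario_pair("sweep_classification", src, tgt, n_samples, L,
                label = "tree inference only")
}

#' @rdname scenario-presets
#' @export
scenario_bottleneck <- function(ne_b, n_samples = 32L, L = 1e5,
                                sigma_bl = 0.3, p_nni = 0.05) {
  stopifnot(ne_b > 0)
  pair <- scenario_tree_inference_only(n_samples, L, sigma_bl, p_nni)
  pair$target$demography <- demography_model(
    c(0, 1000, 2000), c(1e4, ne_b, 1e4),
    sprintf("Ne = %g bottleneck, 1000-2000 generations ago", ne_b))
  pair$label <- sprintf("bottleneck_%g", ne_b)
  pair
}

#' @rdname scenario-presets
#' @export
scenario_extreme <- function(n_samples = 32L, L = 1e5,
                             sigma_bl = 0.3, p_nni = 0.05) {
  pair <- scenario_bottleneck(500, n_samples, L, sigma_bl, p_nni)
  pair$target$rho <- 1e-7
  pair$target$bgs <- bgs_config(genic_span = c(L / 2 - 5000, L / 2 + 5000))
  pair$label <- "extreme"
  pair
}

#' @rdname scenario-presets
#' @export
scenario_relernn_bgs <- function(n_samples = 32L, L = 3e5) {
  src <- list(demography = demography_model(0, 1e4, "equilibrium Ne = 10000"),
              mu_range = c(1.875e-8, 3.125e-8), rho_range = c(0, 6.25e-8))
  tgt <- src
  tgt$bgs <- bgs_config(genic_span = c(1e5, 2e5))
  scenario_pair("rho_regression", src, tgt, n_samples, L,
                label = "relernn_bgs")
}

#' @rdname scenario-presets
#' @export
scenario_relernn_demography <- function(n_samples = 32L, L = 3e5,
                                        source_ne = NULL) {
  tgt <- list(demography = european_demography(),
              mu_range = c(1.875e-8, 3.125e-8), rho_range = c(0, 6.25e-8))
  src <- tgt
  src$demography <- if (is.null(source_ne)) NULL else
    demography_model(0, source_ne, sprintf("equilibrium Ne = %.0f (Watterson-calibrated)",
                                           source_ne))
  scenario_pair("rho_regression", src, tgt, n_samples, L,
                label = "relernn_demography")
}

#' @rdname scenario-presets
#' @export
scenario_no_misspec <- function(task = "rho_regression", n_samples = 32L,
                                L = 3e5) {
  if (task == "rho_regression") {
    src <- list(demography = demography_model(0, 1e4, "equilibrium Ne = 10000"),
                mu_range = c(1.875e-8, 3.125e-8), rho_range = c(0, 6.25e-8))
  } else {
    src <- eq_domain()
  }
  scenario_pair(task, src, src, n_samples, L, label = "no_misspec")
}

#' Calibrate the source-domain equilibrium Ne from target data
#'
#' Mirrors the standard workflow for recombination-rate inference under an
#' unknown demography: simulate (or observe) target-domain data, compute the
#' mean per-bp Watterson estimator across regions, and set the equilibrium
#' source Ne to `mean(theta_W) / (4 * mean(mu))`.
#'
#' @param pair a `scenario_pair` whose target defines the "real" data.
#' @param n_regions number of pilot regions.
#' @param seed integer seed.
#' @return The calibrated Ne (numeric).
#' @export
calibrate_source_ne <- function(pair, n_regions = 100L, seed = 1L) {
  set.seed(seed)
  tgt <- pair$target
  th <- vapply(seq_len(n_regions), function(i) {
    mu <- stats::runif(1L, tgt$mu_range[1], tgt$mu_range[2])
    rho <- stats::runif(1L, tgt$rho_range[1], tgt$rho_range[2])
    r <- sim_region(pair$n_samples, pair$L, mu, rho, tgt$demography,
                    genotypes = FALSE)
    watterson_theta(r$n_sites, pair$n_samples, pair$L)
  }, numeric(1))
  equilibrium_ne(mean(th), mean(tgt$mu_range))
}

# ---- example simulation per domain ---------------------------------------

# One genealogy-task example: returns list(tensor, label). Scaling: F and R
# are divided by n, W by 4*Ne_ref, keeping all channels O(1) for the network.
sim_genealogy_example <- function(domain, n, sweep_label, ne_ref = 1e4) {
  dem <- domain$demography
  if (!is.null(domain$bgs)) dem <- apply_bgs_surrogate(domain$bgs, dem)$demography
  g <- if (sweep_label) {
    s <- stats::runif(1L, domain$sweep_s_range[1], domain$sweep_s_range[2])
    sweep_genealogy(n, dem, sweep_params(s = s))
  } else {
    s <- NA_real_
    neutral_focal_genealogy(n, dem)
  }
  if (!is.null(domain$inference_error)) {
    g <- apply_inference_error(g, domain$inference_error$sigma_bl,
                               domain$inference_error$p_nni)
    if (is.null(g$derived_leaves)) g <- neutral_refocal(g)
  }
  te <- encoding_tensor(encode_genealogy(g))
  te[, , "F"] <- te[, , "F"] / n
  te[, , "R"] <- te[, , "R"] / n
  te[, , "W"] <- te[, , "W"] / (4 * ne_ref)
  list(tensor = te, sweep = sweep_label, s = if (sweep_label) s else NA_real_)
}

# re-draw a focal mutation when a topology move invalidated the clade
neutral_refocal <- function(g) {
  ch <- which(!is.na(g$parent))
  blen <- g$node_time[g$parent[ch]] - g$node_time[ch]
  g$mutation_branch <- ch[sample.int(length(ch), 1L, prob = blen)]
  g$derived_leaves <- sort(descendant_leaves(g, g$mutation_branch))
  g
}

# One recombination-task example under a domain configuration.
sim_rho_example <- function(domain, n, L) {
  dem <- domain$demography
  if (!is.null(domain$bgs)) dem <- apply_bgs_surrogate(domain$bgs, dem)$demography
  rho_range <- if (!is.null(domain$rho_override)) rep(domain$rho_override, 2L) else
    domain$rho_range
  simulate_relernn_example(dem, n = n, L = L, mu_range = domain$mu_range,
                           rho_range = rho_range)
}

#' Pack genotype-matrix examples into a padded network input
#'
#' Sites are the recurrent time steps. Each site row carries the `n`
#' genotypes coded -1 (ancestral) / +1 (derived), the position normalized
#' to `[0, 1]` over the region, the gap to the previous site (normalized
#' by `L` and scaled by `gap_scale` so typical inter-site distances are
#' O(1) for the recurrent gates), and the squared correlation of the
#' site's genotype vector with the previous site's (the local linkage
#' signal recombination-rate estimation keys on; 0 for the first site or
#' when either site is a singleton, whose correlations are pure noise) —
#' `n + 3` features per step. Rows beyond a region's
#' site count are zero-padded and masked. Examples with more than
#' `max_sites` segregating sites keep an evenly spaced subset.
#'
#' @param examples list of [simulate_relernn_example()] results.
#' @param L region length in bp.
#' @param max_sites pad/truncation length; `NULL` uses the dataset maximum.
#' @param gap_scale multiplier applied to the normalized inter-site gaps.
#' @return A list: `x` (`B x max_sites x (n+3)` array), `mask`
#'   (`B x max_sites`), `rho` (labels, per-bp), `mu`, `n_sites`.
#' @export
pack_genotype_examples <- function(examples, L, max_sites = NULL,
                                   gap_scale = 50) {
  ns <- vapply(examples, function(e) e$n_sites, integer(1))
  if (is.null(max_sites)) max_sites <- max(ns, 1L)
  B <- length(examples)
  n <- ncol(examples[[1L]]$genotypes)
  x <- array(0, c(B, max_sites, n + 3L))
  mask <- matrix(0, B, max_sites)
  for (i in seq_len(B)) {
    e <- examples[[i]]
    S <- e$n_sites
    if (S == 0L) next
    keep <- if (S > max_sites) round(seq(1L, S, length.out = max_sites)) else seq_len(S)
    G <- e$genotypes[keep, , drop = FALSE] * 2L - 1L
    p <- e$positions[keep] / L
    k <- length(keep)
    x[i, seq_len(k), seq_len(n)] <- G
    x[i, seq_len(k), n + 1L] <- p
    x[i, seq_len(k), n + 2L] <- gap_scale * c(p[1L], diff(p))
    if (k > 1L) {
      ac <- rowSums(G > 0)
      ok <- ac >= 2L & ac <= n - 2L     # informative: minor count >= 2
      r2 <- numeric(k)
      for (j in 2:k) {
        if (ok[j - 1L] && ok[j]) r2[j] <- stats::cor(G[j - 1L, ], G[j, ])^2
      }
      x[i, seq_len(k), n + 3L] <- r2
    }
    mask[i, seq_len(k)] <- 1
  }
  list(x = x, mask = mask, rho = vapply(examples, function(e) e$rho, numeric(1)),
       mu = vapply(examples, function(e) e$mu, numeric(1)), n_sites = ns)
}

#' Assemble a labeled-source / unlabeled-target dataset
#'
#' Simulates both domains of a scenario and partitions them into the
#' benchmarking splits. Source examples keep their labels throughout;
#' target labels are stripped from the train and validation portions (the
#' protocol treats the target domain as unlabeled "real" data) and retained
#' only in the held-out target test set used for evaluation. For the
#' hypothetical true-model benchmark scenario the stripped training labels
#' are additionally stored under `target$hidden_y`.
#'
#' @param pair a `scenario_pair`.
#' @param n_source number of source examples; the target size is
#'   `n_source / source_target_ratio` unless `n_target` is given.
#' @param n_target optional explicit target size.
#' @param target_sweep_fraction class mixture of the unlabeled target
#'   portion for the classification task (the source stays balanced, and
#'   the target test set is always balanced, mirroring evaluation on a
#'   balanced test set).
#' @param source_target_ratio source:target size ratio (>= 1).
#' @param splits named fractions `train`/`val`/`test` summing to 1.
#' @param seed integer seed; every example is reproducible from
#'   `(scenario, seed, index)`.
#' @param max_sites genotype-task padding length; `NULL` uses the 98th
#'   percentile of the per-example segregating-site counts (the few longer
#'   examples keep an evenly spaced site subset), which bounds the
#'   recurrent sequence length against rare outliers.
#' @return A `dataset_bundle`: `source` (`train`, `val`, `test`, each
#'   `list(x, y)`), `target` (`train_x`, `val_x`, `test = list(x, y)`,
#'   `hidden_y`), and `meta`.
#' @export
assemble_dataset <- function(pair, n_source, n_target = NULL,
                             target_sweep_fraction = 0.5,
                             source_target_ratio = 1,
                             splits = c(train = 0.9, val = 0.02, test = 0.08),
                             seed = 1L, max_sites = NULL) {
  stopifnot(inherits(pair, "scenario_pair"), source_target_ratio >= 1)
  if (abs(sum(splits) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(n_target)) n_target <- round(n_source / source_target_ratio)
  if (n_target < 10L) stop("size error: target domain too small to split")
  set.seed(seed)
  classify <- pair$task == "sweep_classification"
  regression_s <- pair$task == "s_regression"
  genealogy_task <- classify || regression_s
  if (pair$task == "rho_regression" && is.null(pair$source$demography)) {
    ne <- calibrate_source_ne(pair, seed = seed)
    pair$source$demography <- demography_model(
      0, ne, sprintf("equilibrium Ne = %.0f (Watterson-calibrated)", ne))
  }
  n_split <- function(n) {
    k <- c(train = floor(splits[["train"]] * n), val = ceiling(splits[["val"]] * n))
    c(k, test = n - sum(k))
  }
  sim_domain <- function(domain, n_ex, sweep_fraction) {
    if (genealogy_task) {
      n_sw <- min(n_ex, round(sweep_fraction * n_ex))
      labels <- sample(c(rep(TRUE, n_sw), rep(FALSE, n_ex - n_sw)))
      ex <- lapply(seq_len(n_ex), function(i)
        sim_genealogy_example(domain, pair$n_samples, labels[i]))
      k <- pair$n_samples - 1L
      x <- array(0, c(n_ex, k, k, 3L))
      for (i in seq_len(n_ex)) x[i, , , ] <- ex[[i]]$tensor
      y <- if (classify) as.integer(labels) else
        log10(vapply(ex, function(e) ifelse(is.na(e$s), 1e-4, e$s), numeric(1)))
      list(x = x, y = y, sweep = labels)
    } else {
      ex <- lapply(seq_len(n_ex), function(i) sim_rho_example(domain, pair$n_samples, pair$L))
      packed <- pack_genotype_examples(ex, pair$L, max_sites)
      list(packed = packed)
    }
  }
  if (genealogy_task) {
    ks <- n_split(n_source); kt <- n_split(n_target)
    # the selection-coefficient regression task uses sweep examples only;
    # classification keeps a balanced source and a balanced target test set,
    # with the requested mixture in the unlabeled target portion
    base_fr <- if (regression_s) 1 else 0.5
    tgt_fr <- if (regression_s) 1 else target_sweep_fraction
    src <- sim_domain(pair$source, n_source, base_fr)
    tgt_trval <- sim_domain(pair$target, kt[["train"]] + kt[["val"]], tgt_fr)
    tgt_test <- sim_domain(pair$target, kt[["test"]], base_fr)
    is <- split_indices(n_source, ks)
    itv <- seq_len(kt[["train"]])
    bundle_x <- function(d, idx) d$x[idx, , , , drop = FALSE]
    source <- list(train = list(x = bundle_x(src, is$train), y = src$y[is$train]),
                   val = list(x = bundle_x(src, is$val), y = src$y[is$val]),
                   test = list(x = bundle_x(src, is$test), y = src$y[is$test]))
    target <- list(train_x = bundle_x(tgt_trval, itv),
                   val_x = bundle_x(tgt_trval, -itv),
                   test = list(x = tgt_test$x, y = tgt_test$y),
                   hidden_y = tgt_trval$y[itv],
                   hidden_val_y = tgt_trval$y[-itv])
    meta <- list(task = pair$task, scenario = pair$label, seed = seed,
                 n_source = n_source, n_target = n_target,
                 target_sweep_fraction = target_sweep_fraction,
                 source_target_ratio = source_target_ratio, splits = splits)
  } else {
    # simulate both domains first so max_sites can be shared
    ex_s <- lapply(seq_len(n_source), function(i)
      sim_rho_example(pair$source, pair$n_samples, pair$L))
    ex_t <- lapply(seq_len(n_target), function(i)
      sim_rho_example(pair$target, pair$n_samples, pair$L))
    if (is.null(max_sites)) {
      ns <- vapply(c(ex_s, ex_t), function(e) e$n_sites, integer(1))
      max_sites <- max(1L, as.integer(ceiling(stats::quantile(ns, 0.98))))
    }
    ps <- pack_genotype_examples(ex_s, pair$L, max_sites)
    pt <- pack_genotype_examples(ex_t, pair$L, max_sites)
    ks <- n_split(n_source); kt <- n_split(n_target)
    is <- split_indices(n_source, ks); it <- split_indices(n_target, kt)
    gx <- function(p, idx) list(x = p$x[idx, , , drop = FALSE],
                                mask = p$mask[idx, , drop = FALSE])
    # labels in units of 1e-8 / bp for training
    ys <- ps$rho * 1e8; yt <- pt$rho * 1e8
    source <- list(train = list(x = gx(ps, is$train), y = ys[is$train]),
                   val = list(x = gx(ps, is$val), y = ys[is$val]),
                   test = list(x = gx(ps, is$test), y = ys[is$test]))
    target <- list(train_x = gx(pt, it$train),
                   val_x = gx(pt, it$val),
                   test = list(x = gx(pt, it$test), y = yt[it$test]),
                   hidden_y = yt[it$train],
                   hidden_val_y = yt[it$val])
    meta <- list(task = pair$task, scenario = pair$label, seed = seed,
                 n_source = n_source, n_target = n_target,
                 source_target_ratio = source_target_ratio,
                 splits = splits, max_sites = max_sites,
                 source_demography = pair$source$demography$label,
                 target_demography = pair$target$demography$label)
  }
  structure(list(source = source, target = target, meta = meta),
            class = "dataset_bundle")
}

split_indices <- function(n, k) {
  perm <- sample.int(n)
  list(train = perm[seq_len(k[["train"]])],
       val = perm[k[["train"]] + seq_len(k[["val"]])],
       test = perm[k[["train"]] + k[["val"]] + seq_len(k[["test"]])])
}

#' @export
print.dataset_bundle <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<dataset_bundle> %s (%s): source %d (%d/%d/%d), target %d\n",
              m$scenario, m$task, m$n_source,
              n_examples(x$source$train$x), n_examples(x$source$val$x),
              n_examples(x$source$test$x), m$n_target))
  invisible(x)
}

#' Construct a dataset bundle from pre-built arrays
#'
#' Lower-level companion of [assemble_dataset()] for externally simulated or
#' ingested examples.
#'
#' @param source list with `train`, `val`, `test`, each `list(x, y)`.
#' @param target list with `train_x`, `val_x`, `test = list(x, y)`.
#' @param meta metadata list (must include `task`).
#' @return A `dataset_bundle`.
#' @export
dataset_bundle <- function(source, target, meta) {
  stopifnot(!is.null(meta$task))
  structure(list(source = source, target = target, meta = meta),
            class = "dataset_bundle")
}
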