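#' Experiment configuration for the benchmarking protocol
#'
#' @param pair a `scenario_pair` (see [scenario_pair()] and the presets).
#' @param n_source,n_target dataset sizes (source examples are labeled;
#'   target examples are unlabeled except the held-out test set).
#' @param scenarios which benchmarking scenarios to run, from
#'   `"source_matched"` (simulation benchmark: train and test on source),
#'   `"target_matched"` (hypothetical true model: train and test on labeled
#'   target), `"standard"` (train on source, apply to target) and
#'   `"domain_adaptive"` (labeled source + unlabeled target, test on
#'   target).
#' @param training a [training_config()].
#' @param network a [network_spec()] or `NULL` to derive one from the pair.
#' @param replicate_seeds integer vector; one full benchmark per seed.
#' @param target_sweep_fraction,source_target_ratio,splits passed to
#'   [assemble_dataset()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(pair, n_source = 4000L, n_target = NULL,
                              scenarios = c("source_matched", "target_matched",
                                            "standard", "domain_adaptive"),
                              training = training_config(),
                              network = NULL,
                              replicate_seeds = 1:3,
                              target_sweep_fraction = 0.5,
                              source_target_ratio = 1,
                              splits = c(train = 0.9, val = 0.02, test = 0.08)) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  structure(list(pair = pair, n_source = n_source, n_target = n_target,
                 scenarios = scenarios, training = training,
                 network = network, replicate_seeds = replicate_seeds,
                 target_sweep_fraction = target_sweep_fraction,
                 source_target_ratio = source_target_ratio, splits = splits),
            class = "experiment_config")
}

default_network_spec <- function(pair, bundle) {
  if (pair$task == "rho_regression") {
    network_spec("rho_regression",
                 input_shape = c(bundle$meta$max_sites, pair$n_samples + 3L))
  } else {
    k <- pair$n_samples - 1L
    network_spec(pair$task, input_shape = c(k, k, 3L))
  }
}

eval_on <- function(model, x, y, task) {
  pred <- predict(model, x)
  if (task == "sweep_classification") {
    metrics_report(y, pred$P_sweep, task)
  } else if (task == "s_regression") {
    metrics_report(10^y, pred$estimate, task)
  } else {
    metrics_report(y * 1e-8, pred$estimate, task)
  }
}

#' Run the four-scenario benchmark
#'
#' Simulates the domain pair once per replicate seed, trains each requested
#' scenario on it, and evaluates all target-facing scenarios on the
#' identical held-out target test set (`source_matched` uses the matched
#' source test set). For regression tasks, the standard and domain-adaptive
#' models are additionally compared by Welch's t-test on their per-example
#' absolute errors.
#'
#' @param cfg an [experiment_config()].
#' @return A `benchmark_report`: per-replicate, per-scenario
#'   [metrics_report()]s, training histories, the comparison table, and
#'   the resolved configuration.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  pair <- cfg$pair
  reps <- list()
  for (seed in cfg$replicate_seeds) {
    bundle <- assemble_dataset(pair, cfg$n_source, cfg$n_target,
                               target_sweep_fraction = cfg$target_sweep_fraction,
                               source_target_ratio = cfg$source_target_ratio,
                               splits = cfg$splits, seed = seed)
    nspec <- if (is.null(cfg$network)) default_network_spec(pair, bundle) else cfg$network
    tcfg <- cfg$training
    tcfg$seed <- seed
    res <- list(); hists <- list()
    if ("source_matched" %in% cfg$scenarios) {
      set.seed(seed)
      mod <- build_network(nspec)
      tr <- train_standard(mod, bundle$source, tcfg)
      res$source_matched <- eval_on(mod, bundle$source$test$x,
                                    bundle$source$test$y, pair$task)
      hists$source_matched <- tr$history
    }
    if ("target_matched" %in% cfg$scenarios) {
      if (is.null(bundle$target$hidden_y)) {
        stop("configuration error: target_matched needs the hypothetical-true-model labels")
      }
      set.seed(seed)
      mod <- build_network(nspec)
      tr <- train_standard(
        mod,
        list(train = list(x = bundle$target$train_x, y = bundle$target$hidden_y),
             val = list(x = bundle$target$val_x, y = bundle$target$hidden_val_y)),
        tcfg)
      res$target_matched <- eval_on(mod, bundle$target$test$x,
                                    bundle$target$test$y, pair$task)
      hists$target_matched <- tr$history
    }
    if ("standard" %in% cfg$scenarios) {
      set.seed(seed)
      mod_std <- build_network(nspec)
      tr <- train_standard(mod_std, bundle$source, tcfg)
      res$standard <- eval_on(mod_std, bundle$target$test$x,
                              bundle$target$test$y, pair$task)
      hists$standard <- tr$history
    }
    if ("domain_adaptive" %in% cfg$scenarios) {
      set.seed(seed)
      mod_da <- build_network(nspec)
      tr <- train_domain_adaptive(mod_da, bundle, tcfg)
      res$domain_adaptive <- eval_on(mod_da, bundle$target$test$x,
                                     bundle$target$test$y, pair$task)
      hists$domain_adaptive <- tr$history
    }
    comparison <- NULL
    if (!is.null(res$standard) && !is.null(res$domain_adaptive) &&
        pair$task != "sweep_classification") {
      es <- abs(res$standard$predictions$predicted - res$standard$predictions$truth)
      ed <- abs(res$domain_adaptive$predictions$predicted -
                  res$domain_adaptive$predictions$truth)
      wt <- welch_t(es, ed)
      comparison <- data.frame(mae_standard = mean(es), mae_domain_adaptive = mean(ed),
                               t = wt$t, df = wt$df, p = wt$p)
    }
    reps[[as.character(seed)]] <- list(seed = seed, metrics = res,
                                       histories = hists,
                                       comparison = comparison,
                                       meta = bundle$meta)
  }
  structure(list(pair_label = pair$label, task = pair$task,
                 config = cfg, replicates = reps),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %s (%s), %d replicate(s)\n",
              x$pair_label, x$task, length(x$replicates)))
  print(benchmark_summary(x), row.names = FALSE)
  invisible(x)
}

#' Summarize a benchmark report across replicates
#'
#' @param report a [run_benchmark()] result.
#' @return A data.frame with one row per replicate and scenario.
#' @export
benchmark_summary <- function(report) {
  out <- NULL
  for (rep in report$replicates) {
    for (nm in names(rep$metrics)) {
      m <- rep$metrics[[nm]]
      out <- rbind(out, data.frame(
        seed = rep$seed, scenario = nm,
        auprc = if (is.null(m$auprc)) NA_real_ else m$auprc,
        mae = if (is.null(m$mae)) NA_real_ else m$mae,
        rmse = if (is.null(m$rmse)) NA_real_ else m$rmse,
        bias = if (is.null(m$bias)) NA_real_ else m$bias))
    }
  }
  out
}

#' Run the mis-specification severity suite
#'
#' One benchmark per mis-specification degree, from genealogy-inference
#' error alone through increasingly severe bottlenecks to the extreme
#' compound case. The domain classifier's starting validation loss is
#' tabulated per degree alongside AUPRC/RMSE.
#'
#' @param cfg an [experiment_config()]; its `pair` is replaced per degree.
#' @param degrees subset of `"tree_inference_only"`, `"bottleneck_8000"`,
#'   `"bottleneck_5000"`, `"bottleneck_2000"`, `"bottleneck_500"`,
#'   `"extreme"`.
#' @param n_samples,L forwarded to the scenario presets.
#' @return A list of `benchmark_report`s, one per degree, with a `summary`
#'   attribute table.
#' @export
run_misspec_suite <- function(cfg, degrees = c("tree_inference_only",
                                               "bottleneck_8000",
                                               "bottleneck_5000",
                                               "bottleneck_2000",
                                               "bottleneck_500", "extreme"),
                              n_samples = 32L, L = 1e5) {
  presets <- list(
    tree_inference_only = function() scenario_tree_inference_only(n_samples, L),
    bottleneck_8000 = function() scenario_bottleneck(8000, n_samples, L),
    bottleneck_5000 = function() scenario_bottleneck(5000, n_samples, L),
    bottleneck_2000 = function() scenario_bottleneck(2000, n_samples, L),
    bottleneck_500 = function() scenario_bottleneck(500, n_samples, L),
    extreme = function() scenario_extreme(n_samples, L))
  bad <- setdiff(degrees, names(presets))
  if (length(bad)) stop("configuration error: unknown mis-specification preset: ",
                        paste(bad, collapse = ", "))
  reports <- list()
  summ <- NULL
  for (d in degrees) {
    cfg_d <- cfg
    cfg_d$pair <- presets[[d]]()
    rep <- run_benchmark(cfg_d)
    reports[[d]] <- rep
    tab <- benchmark_summary(rep)
    tab$degree <- d
    tab$domain_start_loss <- vapply(rep$replicates, function(r) {
      h <- r$histories$domain_adaptive
      if (is.null(h)) NA_real_ else h$domain_val[1L]
    }, numeric(1))[as.character(tab$seed)]
    summ <- rbind(summ, tab)
  }
  attr(reports, "summary") <- summ
  reports
}

#' Run the class-imbalance and domain-size-ratio suite
#'
#' Varies the sweep fraction of the unlabeled target data and the
#' source:target size ratio for the sweep-classification task; evaluation
#' always uses a balanced target test set.
#'
#' @param cfg an [experiment_config()] with a classification pair.
#' @param sweep_fractions target sweep fractions in `[0, 1]`.
#' @param ratios source:target ratios (>= 1).
#' @return A list of `benchmark_report`s keyed by setting, with a
#'   `summary` attribute table.
#' @export
run_imbalance_suite <- function(cfg, sweep_fractions = c(0.2, 0.5, 0.8),
                                ratios = 1) {
  stopifnot(all(sweep_fractions >= 0 & sweep_fractions <= 1), all(ratios >= 1))
  reports <- list()
  summ <- NULL
  for (fr in sweep_fractions) for (ra in ratios) {
    cfg_i <- cfg
    cfg_i$target_sweep_fraction <- fr
    cfg_i$source_target_ratio <- ra
    key <- sprintf("sweep%.2f_ratio%g", fr, ra)
    rep <- run_benchmark(cfg_i)
    reports[[key]] <- rep
    tab <- benchmark_summary(rep)
    tab$sweep_fraction <- fr
    tab$ratio <- ra
    summ <- rbind(summ, tab)
  }
  attr(reports, "summary") <- summ
  reports
}

#' Write a benchmark report to disk
#'
#' Writes the per-replicate metric summary as TSV, the per-example
#' predictions as TSV, and the resolved configuration plus metrics as JSON.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- benchmark_summary(report)
  utils::write.table(summ, file.path(dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  preds <- NULL
  for (rep in report$replicates) {
    for (nm in names(rep$metrics)) {
      p <- rep$metrics[[nm]]$predictions
      p$scenario <- nm
      p$seed <- rep$seed
      preds <- rbind(preds, p)
    }
  }
  utils::write.table(preds, file.path(dir, "predictions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(pair = report$pair_label, task = report$task,
               n_source = report$config$n_source,
               replicate_seeds = report$config$replicate_seeds,
               scenarios = report$config$scenarios,
               metrics = summ)
  jsonlite::write_json(meta, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
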