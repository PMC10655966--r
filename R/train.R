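#' Training configuration
#'
#' @param batch_size minibatch size (64 in the reference setup).
#' @param lr Adam learning rate.
#' @param max_epochs maximum number of passes over the labeled source data.
#' @param patience early-stopping patience, in epochs, on the label
#'   predictor's validation loss.
#' @param lambda optional gradient-reversal weight override; `NULL` keeps
#'   the weight the network was built with (default 1, i.e. equal weighting
#'   of label-prediction and domain-classification losses).
#' @param lambda_warmup number of initial epochs over which the reversal
#'   weight ramps linearly from 0 to its target (0 disables the ramp; the
#'   constant equal-weight scheme is the reference configuration).
#' @param domain_fraction source share of the domain-classifier half of each
#'   minibatch (default 0.5: 32 source + 32 target at batch size 64).
#' @param seed optional seed for batch shuffling.
#' @param verbose print per-epoch losses.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 64L, lr = 1e-3, max_epochs = 100L,
                            patience = 5L, lambda = NULL, lambda_warmup = 0L,
                            domain_fraction = 0.5, seed = NULL,
                            verbose = FALSE) {
  stopifnot(batch_size > 0, patience >= 1, max_epochs >= 1,
            domain_fraction > 0, domain_fraction <= 1, lambda_warmup >= 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lambda = lambda,
                 lambda_warmup = as.integer(lambda_warmup),
                 domain_fraction = domain_fraction, seed = seed,
                 verbose = verbose),
            class = "training_config")
}

# slice an input container (4-d array, matrix, or list(x, mask)) by batch index
slice_x <- function(x, idx) {
  if (is.list(x)) {
    list(x = x$x[idx, , , drop = FALSE], mask = x$mask[idx, , drop = FALSE])
  } else if (length(dim(x)) == 4L) {
    x[idx, , , , drop = FALSE]
  } else {
    x[idx, , drop = FALSE]
  }
}

n_examples <- function(x) if (is.list(x)) dim(x$x)[1L] else dim(x)[1L]

#' Build the two-component minibatches of one training epoch
#'
#' Each domain-adaptive minibatch has two components: `labeled_source`
#' (`batch_size` labeled source examples fed to the label predictor) and a
#' domain mixture (`domain_source` + `domain_target`, together `batch_size`
#' examples fed to the domain classifier, split by `domain_fraction`). Over
#' one epoch every source example appears exactly once in `labeled_source`;
#' the same source pool is reused for the domain component under an
#' independent shuffle, and the target pool is cycled with reshuffling when
#' smaller than the source pool.
#'
#' @param n_source,n_target pool sizes; `n_target = 0` is a configuration
#'   error (domain-adaptive training requires unlabeled target data).
#' @param cfg a [training_config()].
#' @param domain_seed optional seed for an isolated RNG stream used for the
#'   domain-mixture shuffles, so that the labeled-source epoch permutation
#'   consumes exactly the same draws as standard training (this is what
#'   makes a `lambda = 0` domain-adaptive run reproduce the standard
#'   trajectory bit for bit under a shared seed).
#' @return A list of minibatches, each with integer index vectors
#'   `labeled_source`, `domain_source`, `domain_target`.
#' @export
make_minibatches <- function(n_source, n_target, cfg = training_config(),
                             domain_seed = NULL) {
  if (n_source < 1L) stop("configuration error: empty source stream")
  if (n_target < 1L) stop("configuration error: domain-adaptive mode requires target data")
  b <- cfg$batch_size
  n_ds <- max(1L, round(b * cfg$domain_fraction))
  n_dt <- b - n_ds
  perm_ls <- sample.int(n_source)
  if (!is.null(domain_seed)) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()), add = TRUE)
    set.seed(domain_seed)
  }
  perm_ds <- sample.int(n_source)   # same pool, shuffled differently
  tpool <- sample.int(n_target)
  ti <- 0L
  take_target <- function(k) {
    out <- integer(0)
    while (k > 0L) {
      if (ti >= n_target) { tpool <<- sample.int(n_target); ti <<- 0L }
      take <- min(k, n_target - ti)
      out <- c(out, tpool[ti + seq_len(take)])
      ti <<- ti + take
      k <- k - take
    }
    out
  }
  starts <- seq(1L, n_source, by = b)
  lapply(starts, function(s) {
    idx <- s:min(s + b - 1L, n_source)
    nb <- length(idx)
    nds <- max(1L, round(nb * cfg$domain_fraction))
    list(labeled_source = perm_ls[idx],
         domain_source = perm_ds[idx][seq_len(nds)],
         domain_target = if (nds < nb) take_target(nb - nds) else integer(0))
  })
}

task_loss <- function(task, out, y) {
  if (task == "sweep_classification") xent_loss(out, y) else mse_loss(out, y)
}

eval_label_loss <- function(model, x, y, batch = 256L) {
  n <- n_examples(x)
  tot <- 0
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    out <- stack_forward(model$label_head,
                         stack_forward(model$feature, slice_x(x, idx)))
    tot <- tot + task_loss(model$spec$task, out, y[idx])$loss * length(idx)
  }
  tot / n
}

eval_domain_loss <- function(model, x_src, x_tgt, batch = 256L) {
  tot <- 0; n <- 0
  for (part in list(list(x = x_src, lab = 0L), list(x = x_tgt, lab = 1L))) {
    np <- n_examples(part$x)
    for (s in seq(1L, np, by = batch)) {
      idx <- s:min(s + batch - 1L, np)
      out <- stack_forward(model$domain_head,
                           stack_forward(model$feature, slice_x(part$x, idx)))
      tot <- tot + xent_loss(out, rep(part$lab, length(idx)))$loss * length(idx)
      n <- n + length(idx)
    }
  }
  tot / n
}

check_finite <- function(loss, what) {
  if (!is.finite(loss)) {
    stop(sprintf("training diverged: non-finite %s loss", what))
  }
  loss
}

#' Train the standard (non-adaptive) model
#'
#' Trains feature extractor + label predictor on labeled data with Adam,
#' early-stopping at the epoch with the lowest validation label loss and
#' restoring that checkpoint.
#'
#' @param model a [build_network()] result.
#' @param data list with `train = list(x, y)` and `val = list(x, y)`.
#' @param cfg a [training_config()].
#' @return `model` (trained, best checkpoint restored), invisibly inside a
#'   list that also carries `history` (per-epoch losses) and `best_epoch`.
#' @export
train_standard <- function(model, data, cfg = training_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- n_examples(data$train$x)
  opt <- new.env(parent = emptyenv()); opt$t <- 0L; opt$m <- list(); opt$v <- list()
  layers <- c(model$feature, model$label_head)
  best <- Inf; best_params <- NULL; best_epoch <- 0L; wait <- 0L
  hist <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    tl <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      zero_grads(layers)
      feat <- stack_forward(model$feature, slice_x(data$train$x, idx), train = TRUE)
      out <- stack_forward(model$label_head, feat, train = TRUE)
      ls <- task_loss(model$spec$task, out, data$train$y[idx])
      check_finite(ls$loss, "label")
      dfeat <- stack_backward(model$label_head, ls$grad)
      stack_backward(model$feature, dfeat)
      adam_step(layers, opt, lr = cfg$lr)
      tl <- tl + ls$loss * length(idx)
    }
    vl <- eval_label_loss(model, data$val$x, data$val$y)
    hist <- rbind(hist, data.frame(epoch = epoch, label_train = tl / n,
                                   label_val = vl,
                                   domain_train = NA_real_,
                                   domain_val = NA_real_))
    if (cfg$verbose) message(sprintf("epoch %d: train %.4f val %.4f", epoch, tl / n, vl))
    if (vl < best) {
      best <- vl; best_epoch <- epoch; wait <- 0L
      best_params <- get_params(model)
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best_params)) set_params(model, best_params)
  list(model = model, history = hist, best_epoch = best_epoch)
}

#' Train the domain-adaptive model
#'
#' The two-component minibatch scheme: per step, labeled source examples are
#' fed through feature extractor + label predictor (cross-entropy for
#' classification, mean squared error for regression), and a source/target
#' mixture is fed through feature extractor + gradient reversal + domain
#' classifier (cross-entropy, equal loss weight). Back-propagation from the
#' two components occurs simultaneously: the feature extractor receives the
#' label-loss gradient plus `-lambda` times the domain-loss gradient in a
#' single Adam update. Early stopping follows the label predictor's
#' validation loss only; the domain classifier's validation loss is recorded
#' per epoch.
#'
#' @param model a [build_network()] result.
#' @param bundle a [dataset_bundle()] (needs unlabeled target training data).
#' @param cfg a [training_config()].
#' @return A list: `model`, `history`, `best_epoch`.
#' @export
train_domain_adaptive <- function(model, bundle, cfg = training_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(bundle$target$train_x) || n_examples(bundle$target$train_x) < 1L) {
    stop("configuration error: domain-adaptive mode requires unlabeled target training data")
  }
  if (!is.null(cfg$lambda)) {
    for (l in model$domain_head) if (l$type == "grl") l$lambda <- cfg$lambda
  }
  grl_layers <- Filter(function(l) l$type == "grl", model$domain_head)
  lambda_target <- if (length(grl_layers)) grl_layers[[1L]]$lambda else 1
  xs <- bundle$source$train$x; ys <- bundle$source$train$y
  xt <- bundle$target$train_x
  n <- n_examples(xs)
  opt <- new.env(parent = emptyenv()); opt$t <- 0L; opt$m <- list(); opt$v <- list()
  layers <- all_layers(model)
  best <- Inf; best_params <- NULL; best_epoch <- 0L; wait <- 0L
  hist <- NULL
  dseed_base <- (if (is.null(cfg$seed)) 0L else cfg$seed) + 77003L
  warmup <- if (is.null(cfg$lambda_warmup)) 0L else cfg$lambda_warmup
  for (epoch in seq_len(cfg$max_epochs)) {
    if (warmup > 0L) {
      lam <- lambda_target * min(1, epoch / (warmup + 1))
      for (l in grl_layers) l$lambda <- lam
    }
    batches <- make_minibatches(n, n_examples(xt), cfg,
                                domain_seed = dseed_base + epoch)
    tl <- 0; dl <- 0; nd <- 0
    for (bt in batches) {
      zero_grads(layers)
      # component 1: labeled source through the label predictor
      feat <- stack_forward(model$feature, slice_x(xs, bt$labeled_source), train = TRUE)
      out <- stack_forward(model$label_head, feat, train = TRUE)
      ls <- task_loss(model$spec$task, out, ys[bt$labeled_source])
      check_finite(ls$loss, "label")
      dfeat <- stack_backward(model$label_head, ls$grad)
      stack_backward(model$feature, dfeat)
      # component 2: source/target mixture through GRL + domain classifier
      xmix <- cat_inputs(slice_x(xs, bt$domain_source),
                         slice_x(xt, bt$domain_target))
      dlab <- c(rep(0L, length(bt$domain_source)), rep(1L, length(bt$domain_target)))
      featd <- stack_forward(model$feature, xmix, train = TRUE)
      outd <- stack_forward(model$domain_head, featd, train = TRUE)
      lsd <- xent_loss(outd, dlab)
      check_finite(lsd$loss, "domain")
      dfeatd <- stack_backward(model$domain_head, lsd$grad)
      stack_backward(model$feature, dfeatd)
      adam_step(layers, opt, lr = cfg$lr,
                clip_layers = c(model$feature, model$label_head))
      tl <- tl + ls$loss * length(bt$labeled_source)
      dl <- dl + lsd$loss * length(dlab); nd <- nd + length(dlab)
    }
    vl <- eval_label_loss(model, bundle$source$val$x, bundle$source$val$y)
    dvl <- eval_domain_loss(model, bundle$source$val$x, bundle$target$val_x)
    hist <- rbind(hist, data.frame(epoch = epoch, label_train = tl / n,
                                   label_val = vl, domain_train = dl / nd,
                                   domain_val = dvl))
    if (cfg$verbose) {
      message(sprintf("epoch %d: label %.4f/%.4f domain %.4f/%.4f",
                      epoch, tl / n, vl, dl / nd, dvl))
    }
    if (vl < best) {
      best <- vl; best_epoch <- epoch; wait <- 0L
      best_params <- get_params(model)
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best_params)) set_params(model, best_params)
  list(model = model, history = hist, best_epoch = best_epoch)
}

# concatenate two input containers along the batch dimension
cat_inputs <- function(a, b) {
  if (is.list(a)) {
    da <- dim(a$x); db <- dim(b$x)
    if (db[1L] == 0L) return(a)
    x <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
    x[seq_len(da[1L]), , ] <- a$x
    x[da[1L] + seq_len(db[1L]), , ] <- b$x
    list(x = x, mask = rbind(a$mask, b$mask))
  } else if (length(dim(a)) == 4L) {
    da <- dim(a); db <- dim(b)
    if (db[1L] == 0L) return(a)
    x <- array(0, c(da[1L] + db[1L], da[2:4]))
    x[seq_len(da[1L]), , , ] <- a
    x[da[1L] + seq_len(db[1L]), , , ] <- b
    x
  } else {
    rbind(a, b)
  }
}
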