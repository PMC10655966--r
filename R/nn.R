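#' @title A small neural-network engine with gradient reversal
#' @description The domain-adversarial training scheme at the heart of this
#'   package needs exact control over how gradients from the domain
#'   classifier flow back into the feature extractor, so the layers used
#'   here (dense, 2-D convolution, pooling, GRU, gradient reversal) carry
#'   hand-derived backward passes and are updated with Adam. Layers are
#'   mutable environments: `forward` caches activations, `backward`
#'   consumes the upstream gradient, accumulates parameter gradients and
#'   returns the downstream gradient.
#' @name nn-engine
NULL

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

#' Dense (fully connected) layer
#'
#' @param d_in,d_out input/output widths.
#' @param activation one of `"linear"`, `"relu"`, `"tanh"`, `"sigmoid"`.
#' @return An `nn_layer` environment.
#' @keywords internal
nn_dense <- function(d_in, d_out, activation = "linear") {
  l <- new_layer("dense", activation = activation)
  l$params <- list(W = glorot(d_in, d_out), b = rep(0, d_out))
  l
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; multiplies the incoming gradient by
#' `-lambda` in the backward pass. Inserting it between the feature
#' extractor and the domain classifier turns minimization of the domain
#' cross-entropy into adversarial maximization with respect to the features,
#' which drives feature extraction toward domain invariance.
#'
#' @param lambda non-negative reversal weight (1 gives equal weighting of
#'   the label-prediction and domain-classification losses).
#' @return An `nn_layer` environment.
#' @keywords internal
nn_grl <- function(lambda = 1) {
  stopifnot(lambda >= 0)
  new_layer("grl", lambda = lambda)
}

#' Apply the gradient-reversal forward contract
#'
#' The forward pass of a gradient reversal layer: returns `x` exactly. The
#' backward contract (the gradient of any downstream scalar with respect to
#' the input equals `-lambda` times its gradient with respect to the
#' output) is realized when the op is used as a layer inside a network; see
#' [nn_grl()] and [build_network()].
#'
#' @param x a numeric tensor.
#' @param lambda non-negative reversal weight.
#' @return `x`, unchanged.
#' @export
gradient_reversal <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  x
}

#' GRU layer over padded site sequences
#'
#' A gated recurrent unit scanning the rows (sites) of a genotype-matrix
#' example, with masking of padded rows. The output concatenates the mean
#' of the hidden states over valid steps with the final hidden state
#' (`2 * d_h` features): the mean captures per-site average signal, the
#' final state sequence-level quantities such as the number of segregating
#' sites. Input is a list `x` (array `batch x T x d_in`) and `mask`
#' (`batch x T`, 1 for real sites).
#'
#' @param d_in,d_h input width / hidden size.
#' @return An `nn_layer` environment.
#' @keywords internal
nn_gru <- function(d_in, d_h, use_last = FALSE, summaries = FALSE) {
  l <- new_layer("gru", d_h = d_h, d_in = d_in, use_last = use_last,
                 summaries = summaries)
  l$params <- list(W = glorot(d_in, 3L * d_h),  # [z | r | h] input weights
                   U = glorot(d_h, 3L * d_h),
                   b = rep(0, 3L * d_h))
  l
}

# 2-D convolution (valid padding, stride 1) + ReLU, via im2col.
nn_conv2d <- function(c_in, c_out, k = 3L) {
  l <- new_layer("conv2d", c_in = c_in, c_out = c_out, k = k)
  l$params <- list(W = glorot(k * k * c_in, c_out), b = rep(0, c_out))
  l
}

# 2x2 mean pooling, stride 2 (odd trailing row/col dropped).
nn_meanpool2 <- function() new_layer("meanpool2")

# Global mean pool over the spatial dimensions: B x H x W x C -> B x C.
nn_gpool <- function() new_layer("gpool")

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_forward <- function(l, x, train = FALSE) {
  switch(
    l$type,
    dense = {
      Z <- sweep(x %*% l$params$W, 2L, l$params$b, "+")
      A <- switch(l$activation, linear = Z, relu = pmax(Z, 0),
                  tanh = tanh(Z), sigmoid = sigmoid(Z))
      l$cache <- list(x = x, A = A)
      A
    },
    grl = x,
    gru = gru_forward(l, x),
    conv2d = conv2d_forward(l, x),
    meanpool2 = pool_forward(l, x),
    gpool = {
      d <- dim(x)
      l$cache <- list(dims = d)
      matrix(x, d[1L], prod(d[2:3]) * d[4L])
      # mean over H, W per channel
      out <- apply(array(x, c(d[1L], d[2L] * d[3L], d[4L])), c(1L, 3L), mean)
      matrix(out, d[1L], d[4L])
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, dy) {
  switch(
    l$type,
    dense = {
      x <- l$cache$x; A <- l$cache$A
      dZ <- switch(l$activation,
                   linear = dy,
                   relu = dy * (A > 0),
                   tanh = dy * (1 - A^2),
                   sigmoid = dy * A * (1 - A))
      l$grads$W <- add_grad(l$grads$W, crossprod(x, dZ))
      l$grads$b <- add_grad(l$grads$b, colSums(dZ))
      dZ %*% t(l$params$W)
    },
    grl = -l$lambda * dy,
    gru = gru_backward(l, dy),
    conv2d = conv2d_backward(l, dy),
    meanpool2 = pool_backward(l, dy),
    gpool = {
      d <- l$cache$dims
      sp <- d[2L] * d[3L]
      dx <- array(0, d)
      for (c1 in seq_len(d[4L])) dx[, , , c1] <- dy[, c1] / sp
      dx
    },
    stop("unknown layer type: ", l$type))
}

add_grad <- function(g, delta) if (is.null(g)) delta else g + delta

# ---- GRU forward/backward -------------------------------------------------

gru_forward <- function(l, x) {
  X <- x$x; mask <- x$mask
  d <- dim(X)
  B <- d[1L]; TT <- d[2L]; h <- l$d_h
  # input projections for all gates and timesteps in one BLAS call
  Xmat <- matrix(X, B * TT, d[3L])  # column-major: (b,t) pairs x d_in
  G_in <- sweep(Xmat %*% l$params$W, 2L, l$params$b, "+")  # (B*TT) x 3h
  H <- matrix(0, B, h)
  Hs <- array(0, c(B, TT, h))
  Zs <- array(0, c(B, TT, h)); Rs <- array(0, c(B, TT, h))
  Cs <- array(0, c(B, TT, h))
  U <- l$params$U
  iz <- seq_len(h); ir <- h + iz; ic <- 2L * h + iz
  for (t in seq_len(TT)) {
    rows <- (t - 1L) * B + seq_len(B)
    gi <- G_in[rows, , drop = FALSE]
    HU <- H %*% U
    z <- sigmoid(gi[, iz, drop = FALSE] + HU[, iz, drop = FALSE])
    r <- sigmoid(gi[, ir, drop = FALSE] + HU[, ir, drop = FALSE])
    cc <- tanh(gi[, ic, drop = FALSE] + (r * H) %*% U[, ic, drop = FALSE])
    Hnew <- (1 - z) * H + z * cc
    mt <- mask[, t]
    H <- Hnew * mt + H * (1 - mt)
    Hs[, t, ] <- H; Zs[, t, ] <- z; Rs[, t, ] <- r; Cs[, t, ] <- cc
  }
  nvalid <- pmax(rowSums(mask), 1)
  pooled <- matrix(0, B, h)
  for (t in seq_len(TT)) pooled <- pooled + Hs[, t, ] * mask[, t]
  pooled <- pooled / nvalid
  l$cache <- list(X = X, mask = mask, Hs = Hs, Zs = Zs, Rs = Rs, Cs = Cs,
                  nvalid = nvalid, B = B, TT = TT)
  out <- if (l$use_last) cbind(pooled, H) else pooled
  if (l$summaries) {
    # mask-weighted per-channel input means plus the valid-step fraction:
    # a global-average-pooling skip path past the recurrence
    xm <- matrix(0, B, d[3L])
    for (t in seq_len(TT)) xm <- xm + X[, t, ] * mask[, t]
    out <- cbind(out, xm / nvalid, nvalid / TT)
  }
  out
}

gru_backward <- function(l, dy) {
  cc <- l$cache
  B <- cc$B; TT <- cc$TT; h <- l$d_h
  dsum <- NULL
  if (l$summaries) {
    nsum <- l$d_in + 1L
    dsum <- dy[, ncol(dy) - nsum + seq_len(l$d_in), drop = FALSE]
    dy <- dy[, seq_len(ncol(dy) - nsum), drop = FALSE]
  }
  dpool <- dy[, seq_len(h), drop = FALSE]
  U <- l$params$U
  iz <- seq_len(h); ir <- h + iz; ic <- 2L * h + iz
  dW <- matrix(0, l$d_in, 3L * h); dU <- matrix(0, h, 3L * h)
  db <- rep(0, 3L * h)
  dX <- array(0, c(B, TT, l$d_in))
  dH <- if (l$use_last) dy[, h + seq_len(h), drop = FALSE] else
    matrix(0, B, h)  # gradient of the final state, when exposed
  for (t in rev(seq_len(TT))) {
    mt <- cc$mask[, t]
    dH <- dH + dpool * (mt / cc$nvalid)
    Hprev <- if (t > 1L) cc$Hs[, t - 1L, ] else matrix(0, B, h)
    z <- cc$Zs[, t, ]; r <- cc$Rs[, t, ]; ch <- cc$Cs[, t, ]
    # masked steps carry H through untouched
    dHn <- dH * mt
    dHcarry <- dH * (1 - mt)
    dz <- dHn * (ch - Hprev) * z * (1 - z)
    dc <- dHn * z * (1 - ch^2)
    dHp <- dHn * (1 - z)
    dRH <- dc %*% t(U[, ic, drop = FALSE])
    dr <- dRH * Hprev * r * (1 - r)
    dHp <- dHp + dRH * r
    dHp <- dHp + dz %*% t(U[, iz, drop = FALSE]) + dr %*% t(U[, ir, drop = FALSE])
    Xt <- matrix(cc$X[, t, ], B, l$d_in)
    dgates <- cbind(dz, dr, dc)
    dW <- dW + crossprod(Xt, dgates)
    dU[, iz] <- dU[, iz] + crossprod(Hprev, dz)
    dU[, ir] <- dU[, ir] + crossprod(Hprev, dr)
    dU[, ic] <- dU[, ic] + crossprod(r * Hprev, dc)
    db <- db + colSums(dgates)
    dX[, t, ] <- dz %*% t(l$params$W[, iz, drop = FALSE]) +
      dr %*% t(l$params$W[, ir, drop = FALSE]) +
      dc %*% t(l$params$W[, ic, drop = FALSE])
    dH <- dHp + dHcarry
  }
  l$grads$W <- add_grad(l$grads$W, dW)
  l$grads$U <- add_grad(l$grads$U, dU)
  l$grads$b <- add_grad(l$grads$b, db)
  if (!is.null(dsum)) {
    for (t in seq_len(TT)) {
      dX[, t, ] <- dX[, t, ] + (dsum / cc$nvalid) * cc$mask[, t]
    }
  }
  list(x = dX, mask = cc$mask)
}

# ---- conv / pooling -------------------------------------------------------

# Column index map for im2col on an H x W x C image, valid padding, stride 1.
im2col_index <- function(H, W, C, k) {
  OH <- H - k + 1L; OW <- W - k + 1L
  # flattened (H, W, C) position of each patch element, per output pixel
  base <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * H, "+"))  # k x k block
  chan <- (seq_len(C) - 1L) * H * W
  patch <- as.vector(outer(base, chan, "+"))                        # k*k*C
  tl <- as.vector(outer(seq_len(OH), (seq_len(OW) - 1L) * H, "+"))  # top-left corners
  idx <- outer(patch - 1L, tl, "+")                                 # (k*k*C) x (OH*OW)
  list(idx = idx, OH = OH, OW = OW)
}

conv2d_forward <- function(l, x) {
  d <- dim(x)
  B <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  key <- paste(H, W, C, sep = "x")
  if (is.null(l$imap) || !identical(l$imap_key, key)) {
    l$imap <- im2col_index(H, W, C, l$k)
    l$imap_key <- key
  }
  im <- l$imap
  K <- nrow(im$idx); Q <- ncol(im$idx)
  Xf <- matrix(x, B, H * W * C)
  Xc <- Xf[, as.vector(im$idx), drop = FALSE]           # B x (K*Q)
  M <- matrix(aperm(array(Xc, c(B, K, Q)), c(1L, 3L, 2L)), B * Q, K)
  Z <- sweep(M %*% l$params$W, 2L, l$params$b, "+")
  A <- pmax(Z, 0)
  l$cache <- list(M = M, A = A, B = B, dims = d)
  array(A, c(B, im$OH, im$OW, l$c_out))
}

conv2d_backward <- function(l, dy) {
  im <- l$imap
  cc <- l$cache
  B <- cc$B
  K <- nrow(im$idx); Q <- ncol(im$idx)
  dZ <- matrix(dy, B * Q, l$c_out) * (cc$A > 0)
  l$grads$W <- add_grad(l$grads$W, crossprod(cc$M, dZ))
  l$grads$b <- add_grad(l$grads$b, colSums(dZ))
  dM <- dZ %*% t(l$params$W)                            # (B*Q) x K
  dXc <- matrix(aperm(array(dM, c(B, Q, K)), c(1L, 3L, 2L)), B, K * Q)
  pos <- as.vector(im$idx)
  rs <- rowsum(t(dXc), pos)                             # unique pos x B
  dXf <- matrix(0, B, prod(cc$dims[2:4]))
  dXf[, as.integer(rownames(rs))] <- t(rs)
  array(dXf, cc$dims)
}

pool_forward <- function(l, x) {
  d <- dim(x)
  OH <- d[2L] %/% 2L; OW <- d[3L] %/% 2L
  i1 <- seq_len(OH) * 2L - 1L; j1 <- seq_len(OW) * 2L - 1L
  y <- (x[, i1, j1, , drop = FALSE] + x[, i1 + 1L, j1, , drop = FALSE] +
          x[, i1, j1 + 1L, , drop = FALSE] + x[, i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
  l$cache <- list(dims = d, OH = OH, OW = OW)
  y
}

pool_backward <- function(l, dy) {
  cc <- l$cache
  dx <- array(0, cc$dims)
  i1 <- seq_len(cc$OH) * 2L - 1L; j1 <- seq_len(cc$OW) * 2L - 1L
  q <- dy / 4
  dx[, i1, j1, ] <- q; dx[, i1 + 1L, j1, ] <- q
  dx[, i1, j1 + 1L, ] <- q; dx[, i1 + 1L, j1 + 1L, ] <- q
  dx
}

# ---- stacks and the DANN assembly ----------------------------------------

stack_forward <- function(layers, x, train = FALSE) {
  for (l in layers) x <- layer_forward(l, x, train)
  x
}

stack_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

zero_grads <- function(layers) {
  for (l in layers) l$grads <- list()
  invisible(NULL)
}

#' Network specification for a task
#'
#' @param task `"sweep_classification"`, `"s_regression"` or
#'   `"rho_regression"`.
#' @param input_shape for the genealogy tasks, `c(n-1, n-1, 3)` (the stacked
#'   F/W/R channels); for `rho_regression`, `c(max_sites, d_in)` with
#'   `d_in = n_samples + 2` (genotypes coded -1/1 plus normalized position
#'   and inter-site gap).
#' @param lambda gradient-reversal weight (default 1: equal weighting of the
#'   label and domain losses).
#' @param conv_channels channel widths of the convolutional feature-extractor
#'   blocks (genealogy input).
#' @param hidden GRU hidden size (genotype input).
#' @param feature_dim width of the shared feature vector both heads consume.
#' @param gru_last expose the GRU's final hidden state alongside the
#'   mean-pooled states (genotype input).
#' @return A `network_spec` list.
#' @export
network_spec <- function(task = c("sweep_classification", "s_regression",
                                  "rho_regression"),
                         input_shape, lambda = 1,
                         conv_channels = c(8L, 16L), hidden = 16L,
                         feature_dim = 16L, gru_last = FALSE) {
  task <- match.arg(task)
  structure(list(task = task, input_shape = input_shape, lambda = lambda,
                 conv_channels = conv_channels, hidden = hidden,
                 feature_dim = feature_dim, gru_last = gru_last),
            class = "network_spec")
}

#' Assemble a domain-adversarial network
#'
#' Builds the three-component architecture: a feature extractor (a small
#' convolutional stack for genealogy-matrix input, a masked GRU stack for
#' genotype-matrix input), a label predictor, and a domain classifier
#' attached to the same feature vector through a gradient reversal layer.
#' The standard (non-adaptive) variant is the identical network trained with
#' the domain branch detached.
#'
#' @param spec a [network_spec()].
#' @param seed optional seed for the parameter initialization.
#' @return An object of class `"dann_network"` with addressable components
#'   `feature`, `label_head` and `domain_head` (lists of layers).
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  fd <- spec$feature_dim
  if (spec$task == "rho_regression") {
    if (length(spec$input_shape) != 2L) {
      stop("construction error: rho_regression expects input_shape c(max_sites, d_in)")
    }
    gl <- isTRUE(spec$gru_last)
    d_in <- spec$input_shape[2L]
    feature <- list(nn_gru(d_in, spec$hidden, use_last = gl, summaries = TRUE),
                    nn_dense((1L + gl) * spec$hidden + d_in + 1L, fd, "relu"))
  } else {
    if (length(spec$input_shape) != 3L || spec$input_shape[3L] != 3L) {
      stop("construction error: genealogy tasks expect input_shape c(n-1, n-1, 3)")
    }
    ch <- spec$conv_channels
    layers <- list()
    cin <- 3L
    hw <- spec$input_shape[1:2]
    for (co in ch) {
      layers <- c(layers, list(nn_conv2d(cin, co), nn_meanpool2()))
      hw <- (hw - 2L) %/% 2L
      if (any(hw < 1L)) stop("construction error: input too small for the conv stack")
      cin <- co
    }
    feature <- c(layers, list(nn_gpool(), nn_dense(cin, fd, "relu")))
  }
  out_dim <- if (spec$task == "sweep_classification") 2L else 1L
  label_head <- list(nn_dense(fd, 8L, "relu"), nn_dense(8L, out_dim, "linear"))
  domain_head <- list(nn_grl(spec$lambda),
                      nn_dense(fd, 8L, "relu"), nn_dense(8L, 2L, "linear"))
  structure(list(spec = spec, feature = feature, label_head = label_head,
                 domain_head = domain_head),
            class = "dann_network")
}

#' @export
print.dann_network <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<dann_network> task = %s | parameters: total %d (feature %d, label %d, domain %d)\n",
              x$spec$task, pc$total, pc$feature, pc$label, pc$domain))
  invisible(x)
}

#' Count trainable parameters per component
#'
#' @param model a [build_network()] result.
#' @return A list with `feature`, `label`, `domain` and `total` counts.
#' @export
count_parameters <- function(model) {
  cnt <- function(layers) sum(vapply(layers, function(l)
    sum(vapply(l$params, length, integer(1))), numeric(1)))
  f <- cnt(model$feature); lb <- cnt(model$label_head); d <- cnt(model$domain_head)
  list(feature = f, label = lb, domain = d, total = f + lb + d)
}

all_layers <- function(model, domain = TRUE) {
  c(model$feature, model$label_head, if (domain) model$domain_head)
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict from a trained network
#'
#' Deterministic inference (no parameter or statistics updates). For
#' classification the result holds the probability of neutrality `P_neu`
#' (class 0) and the sweep probability; for regression, point estimates on
#' the natural scale (selection coefficients are trained as `log10(s)`,
#' recombination rates in units of 1e-8/bp, and back-transformed here).
#'
#' @param object a `dann_network`.
#' @param batch input batch shaped per the network spec.
#' @param type `"label"` (default) or `"domain"` (the two-way domain
#'   probabilities).
#' @param ... unused.
#' @return A data.frame: `P_neu`/`P_sweep` for classification, `estimate`
#'   for regression, or `P_source`/`P_target` for `type = "domain"`.
#' @export
predict.dann_network <- function(object, batch, type = c("label", "domain"),
                                 ...) {
  type <- match.arg(type)
  feat <- stack_forward(object$feature, batch)
  if (type == "domain") {
    p <- softmax(stack_forward(object$domain_head, feat))
    return(data.frame(P_source = p[, 1L], P_target = p[, 2L]))
  }
  out <- stack_forward(object$label_head, feat)
  switch(object$spec$task,
         sweep_classification = {
           p <- softmax(out)
           data.frame(P_neu = p[, 1L], P_sweep = p[, 2L])
         },
         s_regression = data.frame(estimate = 10^out[, 1L]),
         rho_regression = data.frame(estimate = out[, 1L] * 1e-8))
}

# cross-entropy on logits; labels are 0-based integers
xent_loss <- function(logits, labels) {
  p <- softmax(logits)
  idx <- cbind(seq_along(labels), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, grad = d / length(labels))
}

mse_loss <- function(pred, y) {
  r <- pred[, 1L] - y
  list(loss = mean(r^2), grad = matrix(2 * r / length(y), ncol = 1L))
}

# Adam step over a set of layers; `state` is an environment carrying the
# step counter and per-parameter moments. Gradients are jointly rescaled to
# a global norm of at most `clip` first (back-propagation through a
# hundred-plus recurrent steps occasionally explodes otherwise). The norm
# is measured over `clip_layers` — the feature-extractor/label path whose
# recurrence the clip guards — and the resulting factor is applied to every
# layer, which keeps a lambda = 0 domain-adaptive update bitwise identical
# to the standard one.
adam_step <- function(layers, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5, clip_layers = layers) {
  if (is.finite(clip)) {
    sq <- 0
    for (l in clip_layers) for (g in l$grads) sq <- sq + sum(g^2)
    if (sq > clip^2) {
      sc <- clip / sqrt(sq)
      for (l in layers) for (nm in names(l$grads)) {
        l$grads[[nm]] <- l$grads[[nm]] * sc
      }
    }
  }
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      key <- paste0(i, ".", nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      l$params[[nm]] <- l$params[[nm]] -
        lr * (state$m[[key]] / b1t) / (sqrt(state$v[[key]] / b2t) + eps)
    }
  }
  invisible(NULL)
}

get_params <- function(model) {
  lapply(all_layers(model), function(l) l$params)
}

set_params <- function(model, saved) {
  ls0 <- all_layers(model)
  for (i in seq_along(ls0)) ls0[[i]]$params <- saved[[i]]
  invisible(model)
}
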