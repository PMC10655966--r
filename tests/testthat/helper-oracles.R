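# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: branch spans are counted by direct
# enumeration over every branch, and metrics are recomputed from first
# principles.

# Brute-force F/W/R computation: enumerate every branch's closed lifespan
# [child_time, parent_time] and test containment of each window, cell by
# cell, with plain loops.
oracle_encode <- function(g) {
  n <- g$n
  tall <- c(0, sort(g$node_time[(n + 1L):(2L * n - 1L)]))
  child <- which(!is.na(g$parent))
  lo <- g$node_time[child]
  hi <- g$node_time[g$parent[child]]
  derived_nodes <- if (!is.null(g$derived_leaves)) {
    mb <- g$mutation_branch
    keep <- rep(FALSE, 2L * n - 1L)
    for (v in seq_len(2L * n - 1L)) {
      u <- v
      while (!is.na(u)) {
        if (u == mb) { keep[v] <- TRUE; break }
        u <- g$parent[u]
      }
    }
    which(keep)
  } else integer(0)
  k <- n - 1L
  F <- matrix(0L, k, k); W <- matrix(0, k, k); R <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    a <- tall[n - i]       # t_{n-1-i}, recent endpoint
    b <- tall[n - j + 1L]  # t_{n-j}, ancient endpoint
    W[i, j] <- b - a
    for (ci in seq_along(child)) {
      if (lo[ci] <= a && hi[ci] >= b) {
        F[i, j] <- F[i, j] + 1L
        if (child[ci] %in% derived_nodes) R[i, j] <- R[i, j] + 1L
      }
    }
  }
  list(F = F, W = W, R = R)
}

# Average-precision AUPRC from first principles: iterate distinct
# thresholds, count TP/FP at each by explicit comparison.
oracle_auprc <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    recall <- tp / P
    ap <- ap + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  ap
}

# A quick random genealogy with exponential coalescent times (independent of
# the package's demography machinery beyond the constructor).
rand_tree <- function(n) {
  parent <- rep(NA_integer_, 2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pair <- sample(k, 2L)
    parent[active[pair]] <- nxt
    node_time[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  genealogy(parent, node_time)
}

# attach a random focal mutation (proper clade) to a genealogy
with_random_focal <- function(g) {
  ch <- which(!is.na(g$parent))
  g$mutation_branch <- sample(ch, 1L)
  g$derived_leaves <- sort(popdann:::descendant_leaves(g, g$mutation_branch))
  g
}

eq_demog <- function(ne = 1e4) demography_model(0, ne, "test equilibrium")
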