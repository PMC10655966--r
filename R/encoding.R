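#' Encode a genealogy as stacked lower-triangular matrices
#'
#' A ranked genealogy with `n` taxa and strictly increasing coalescent times
#' `0 = t_0 < t_1 < ... < t_{n-1}` is encoded by three `(n-1) x (n-1)`
#' lower-triangular matrices, indexed so that row/column 1 corresponds to the
#' most ancient inter-coalescent window:
#'
#' * `W[i, j] = t_{n-j} - t_{n-1-i}` for `i >= j`: the time span between the
#'   two coalescent events bounding the window.
#' * `F[i, j]`: the number of branches whose closed lifespan
#'   `[child_time, parent_time]` covers the whole window
#'   `[t_{n-1-i}, t_{n-j}]`. On the diagonal `F[k, k] = k + 1`.
#' * `R[i, j]`: the same count restricted to derived-carrying branches — the
#'   branch on which the focal mutation occurred plus every branch inside the
#'   clade it subtends. Requires a focal site (`derived_leaves`).
#'
#' `F` is a bijective encoding of the ranked tree shape (see [decode_F()]),
#' and the reversed diagonal of `W` recovers the coalescent times by
#' cumulative summation, so `F` and `W` jointly carry the entire genealogy.
#'
#' @param g a [genealogy()].
#' @param channels which matrices to compute; `R` requires `g$derived_leaves`.
#' @return An object of class `"encoded_genealogy"`: list with elements `F`,
#'   `W`, and (when requested) `R`, plus `n`. With all three channels the
#'   result stacks to an `(n-1) x (n-1) x 3` array via [encoding_tensor()].
#' @examples
#' g <- genealogy(parent = c(4L, 4L, 5L, 5L, NA),
#'                node_time = c(0, 0, 0, 1, 3),
#'                derived_leaves = 3L)
#' enc <- encode_genealogy(g)
#' enc$F  # rbind(c(2, 0), c(1, 3))
#' @export
encode_genealogy <- function(g, channels = c("F", "W", "R")) {
  validate_genealogy(g)
  n <- g$n
  channels <- match.arg(channels, c("F", "W", "R"), several.ok = TRUE)
  if ("R" %in% channels && is.null(g$derived_leaves)) {
    if (identical(sort(channels), sort(c("F", "W", "R")))) {
      channels <- c("F", "W")  # default call on a tree without a focal site
    } else {
      stop("encoding error: R channel requested but the genealogy has no derived_leaves")
    }
  }
  tc <- coalescent_times(g)           # t_1 ... t_{n-1}
  tall <- c(0, tc)                    # t_0 ... t_{n-1}
  k <- n - 1L
  ii <- seq_len(k)
  recent <- tall[n - ii]              # t_{n-1-i}, window's recent endpoint, i = 1..n-1
  ancient <- tall[n - ii + 1L]        # t_{n-j},   window's ancient endpoint, j = 1..n-1
  child <- which(!is.na(g$parent))
  tv <- g$node_time[child]
  tp <- g$node_time[g$parent[child]]
  low <- lower.tri(matrix(0, k, k), diag = TRUE)
  span_counts <- function(nodes) {
    sel <- child %in% nodes
    # A[i, b] = branch b born no later than the recent endpoint of row i
    # B[j, b] = branch b dies no earlier than the ancient endpoint of col j
    A <- outer(recent, tv[sel], ">=")
    B <- outer(ancient, tp[sel], "<=")
    M <- A %*% t(B) * 1
    M[!low] <- 0
    storage.mode(M) <- "integer"
    M
  }
  out <- list(n = n)
  if ("F" %in% channels) out$F <- span_counts(child)
  if ("W" %in% channels) {
    W <- outer(rep(1, k), ancient) - outer(recent, rep(1, k))
    W[!low] <- 0
    out$W <- W
  }
  if ("R" %in% channels) out$R <- span_counts(derived_branch_nodes(g))
  structure(out, class = "encoded_genealogy")
}

#' @export
print.encoded_genealogy <- function(x, ...) {
  cat(sprintf("<encoded_genealogy> n = %d (%d x %d channels: %s)\n",
              x$n, x$n - 1L, x$n - 1L,
              paste(intersect(c("F", "W", "R"), names(x)), collapse = ", ")))
  invisible(x)
}

#' Stack an encoded genealogy into a 3-channel array
#'
#' @param enc an [encode_genealogy()] result holding `F`, `W` and `R`.
#' @return An `(n-1) x (n-1) x 3` numeric array (channels F, W, R), e.g.
#'   `127 x 127 x 3` for 128 taxa.
#' @export
encoding_tensor <- function(enc) {
  stopifnot(inherits(enc, "encoded_genealogy"),
            all(c("F", "W", "R") %in% names(enc)))
  k <- enc$n - 1L
  array(c(enc$F, enc$W, enc$R), dim = c(k, k, 3L),
        dimnames = list(NULL, NULL, c("F", "W", "R")))
}

#' Count branches spanning a time window
#'
#' The oracle primitive behind [encode_genealogy()]: the number of branches
#' whose closed lifespan `[child_time, parent_time]` contains the full window
#' `[t_recent, t_ancient]` (branches born or dying exactly at an endpoint
#' count).
#'
#' @param g a [genealogy()].
#' @param t_recent,t_ancient window endpoints in generations,
#'   `0 <= t_recent <= t_ancient <= TMRCA`.
#' @param derived_only restrict the count to derived-carrying branches.
#' @return Integer branch count.
#' @export
branch_span_count <- function(g, t_recent, t_ancient, derived_only = FALSE) {
  validate_genealogy(g)
  if (t_recent < 0 || t_ancient > tmrca(g) || t_recent > t_ancient) {
    stop("domain error: need 0 <= t_recent <= t_ancient <= TMRCA")
  }
  nodes <- if (derived_only) derived_branch_nodes(g) else
    which(!is.na(g$parent))
  sum(g$node_time[nodes] <= t_recent &
        g$node_time[g$parent[nodes]] >= t_ancient)
}

# ---- ranked tree shapes and the exhaustive decoder ------------------------

# Enumerate every labeled coalescent history on n leaves as a (n-1) x 2
# matrix of merged node indices (merge k creates node n + k), together with
# the F matrix of the induced ranked shape (F depends only on the shape, not
# on merge times; unit-spaced times are used).
enumerate_labeled_histories <- function(n) {
  out <- list()
  recurse <- function(active, merges) {
    if (length(active) == 1L) {
      out[[length(out) + 1L]] <<- merges
      return(invisible(NULL))
    }
    k <- nrow(merges) + 1L
    idx <- utils::combn(length(active), 2L)
    for (c1 in seq_len(ncol(idx))) {
      a <- active[idx[1L, c1]]
      b <- active[idx[2L, c1]]
      recurse(c(setdiff(active, c(a, b)), n + k),
              rbind(merges, c(a, b)))
    }
  }
  recurse(seq_len(n), matrix(integer(0), 0L, 2L))
  out
}

history_to_genealogy <- function(n, merges) {
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  node_time <- numeric(m)
  for (k in seq_len(nrow(merges))) {
    parent[merges[k, ]] <- n + k
    node_time[n + k] <- k
  }
  genealogy(parent, node_time, validate = FALSE)
}

# Canonical string of the ranked tree shape (label-free): recursive sorted
# representation of subtrees annotated with coalescent ranks.
ranked_shape_key <- function(g) {
  ch <- children_list(g)
  rank_of <- integer(2L * g$n - 1L)
  internal <- (g$n + 1L):(2L * g$n - 1L)
  rank_of[internal][order(g$node_time[internal])] <- seq_len(g$n - 1L)
  key <- function(v) {
    if (v <= g$n) return("L")
    kids <- sort(vapply(ch[[v]], key, character(1)))
    sprintf("(%s,%s)%d", kids[1L], kids[2L], rank_of[v])
  }
  key(which(is.na(g$parent)))
}

#' Enumerate all ranked tree shapes on n leaves
#'
#' Exhaustively generates labeled coalescent histories and deduplicates them
#' by a canonical label-free shape key. Intended for small `n` (the number of
#' labeled histories grows as `n! (n-1)! / 2^(n-1)`).
#'
#' @param n leaf count, `2 <= n <= 7`.
#' @return A list with one element per distinct ranked shape: `genealogy` (a
#'   representative with unit-spaced coalescent times), `key` (canonical
#'   shape string) and `F` (its topology matrix).
#' @export
ranked_tree_shapes <- function(n) {
  stopifnot(n >= 2L, n <= 7L)
  hists <- enumerate_labeled_histories(n)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (h in hists) {
    g <- history_to_genealogy(n, h)
    kk <- ranked_shape_key(g)
    if (is.null(seen[[kk]])) {
      seen[[kk]] <- TRUE
      out[[length(out) + 1L]] <-
        list(genealogy = g, key = kk, F = encode_genealogy(g, "F")$F)
    }
  }
  out
}

#' Decode a topology matrix back to its ranked tree shape
#'
#' Inverts the `F` channel of [encode_genealogy()] by exhaustive search over
#' every ranked tree shape on `n` leaves — deliberately brute-force, so that
#' it can serve as an independent verification of the encoding's claimed
#' bijectivity on small instances.
#'
#' @param F an `(n-1) x (n-1)` lower-triangular integer matrix with diagonal
#'   `F[k, k] = k + 1`; `n - 1 <= 6`.
#' @return The unique matching ranked shape as returned by
#'   [ranked_tree_shapes()] (elements `genealogy`, `key`, `F`).
#' @export
decode_F <- function(F) {
  F <- as.matrix(F)
  k <- nrow(F)
  if (k != ncol(F) || k < 1L || k > 6L) {
    stop("decode_F is a test-scale operation: F must be square with n - 1 <= 6")
  }
  if (any(F[upper.tri(F)] != 0) || any(diag(F) != seq_len(k) + 1L)) {
    stop("invalid-encoding error: F is not lower-triangular with diagonal k + 1")
  }
  shapes <- ranked_tree_shapes(k + 1L)
  hit <- Filter(function(s) all(s$F == F), shapes)
  if (length(hit) == 0L) stop("invalid-encoding error: no ranked tree shape matches F")
  if (length(hit) > 1L) {
    stop("bijectivity-violation error: multiple ranked tree shapes share this F matrix")
  }
  hit[[1L]]
}

#' Verify the invariants of an encoded genealogy
#'
#' Checks the diagonal identity `F[k, k] = k + 1`, row/column monotonicity of
#' `F`, the telescoping property of `W`, elementwise dominance
#' `0 <= R <= F`, and strict lower-triangularity of all channels.
#'
#' @param enc an [encode_genealogy()] result.
#' @return `TRUE` invisibly; errors name the violated invariant.
#' @export
check_encoding_invariants <- function(enc) {
  k <- enc$n - 1L
  up <- upper.tri(matrix(0, k, k))
  F <- enc$F
  if (!all(diag(F) == seq_len(k) + 1L)) stop("diagonal identity F[k,k] = k+1 violated")
  if (any(F[up] != 0)) stop("F not lower-triangular")
  for (j in seq_len(k)) {
    col <- F[j:k, j]
    if (is.unsorted(rev(col))) stop("column monotonicity of F violated")
  }
  for (i in seq_len(k)) {
    row <- F[i, seq_len(i)]
    if (is.unsorted(row)) stop("row monotonicity of F violated")
  }
  if (!is.null(enc$W)) {
    W <- enc$W
    if (any(W[up] != 0)) stop("W not lower-triangular")
    d <- diag(W)
    for (i in seq_len(k)) for (j in seq_len(i)) {
      if (abs(W[i, j] - sum(d[j:i])) > 1e-8 * max(1, W[i, j])) {
        stop("telescoping property of W violated")
      }
    }
  }
  if (!is.null(enc$R)) {
    if (any(enc$R < 0) || any(enc$R > F)) stop("dominance 0 <= R <= F violated")
    if (any(enc$R[up] != 0)) stop("R not lower-triangular")
  }
  invisible(TRUE)
}
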