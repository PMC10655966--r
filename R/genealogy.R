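#' Construct a ranked genealogy at a focal site
#'
#' A genealogy is a binary, ultrametric (all tips sampled at the present)
#' coalescent tree on `n` contemporaneous haploid samples, with node times in
#' generations and, optionally, the set of leaves carrying the derived allele
#' at a focal site. Nodes are indexed `1..n` for leaves and `(n+1)..(2n-1)`
#' for internal (coalescent) nodes; the root is the oldest internal node.
#'
#' Coalescent times must be strictly increasing after tie-breaking: exact ties
#' (possible in trees ingested from discrete-generation simulators) are
#' resolved by adding `k * eps` (with `eps` equal to 1e-9 of the tree height)
#' in node-index order, so that every genealogy has a well-defined ranking.
#'
#' @param parent integer vector of length `2n - 1`; `parent[v]` is the parent
#'   node of `v`, `NA` for the root.
#' @param node_time numeric vector of length `2n - 1`; node times in
#'   generations. Leaves (nodes `1..n`) must be at time 0; internal times
#'   must be positive.
#' @param derived_leaves optional integer vector of leaf indices carrying the
#'   derived allele at the focal site. Must be a proper, non-empty subset of
#'   the leaves and must form a clade (unless `mutation_branch` is given, in
#'   which case it must equal that branch's descendant leaf set).
#' @param mutation_branch optional node index: the branch (stem edge above
#'   this node) on which the focal mutation occurred. Defaults to the stem of
#'   the minimal clade containing exactly `derived_leaves`.
#' @param validate logical; run the structural checks (default `TRUE`).
#' @return An object of class `"genealogy"`: a list with elements `n`,
#'   `parent`, `node_time`, `derived_leaves`, `mutation_branch`.
#' @examples
#' # 3-leaf caterpillar: leaves 1,2 coalesce at t=1, then with leaf 3 at t=3
#' g <- genealogy(parent = c(4L, 4L, 5L, 5L, NA),
#'                node_time = c(0, 0, 0, 1, 3),
#'                derived_leaves = 3L)
#' tmrca(g)
#' @export
genealogy <- function(parent, node_time, derived_leaves = NULL,
                      mutation_branch = NULL, validate = TRUE) {
  m <- length(parent)
  if (m != length(node_time) || m < 3L || m %% 2L == 0L) {
    stop("parent/node_time must have equal odd length 2n-1 >= 3")
  }
  n <- (m + 1L) %/% 2L
  g <- structure(
    list(n = n, parent = as.integer(parent), node_time = as.numeric(node_time),
         derived_leaves = if (is.null(derived_leaves)) NULL else
           sort(unique(as.integer(derived_leaves))),
         mutation_branch = if (is.null(mutation_branch)) NULL else
           as.integer(mutation_branch)),
    class = "genealogy")
  g <- break_time_ties(g)
  if (validate) validate_genealogy(g)
  if (!is.null(g$derived_leaves) && is.null(g$mutation_branch)) {
    g$mutation_branch <- derived_clade_stem(g)
  }
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> n = %d taxa, TMRCA = %.4g generations\n",
              x$n, tmrca(x)))
  if (!is.null(x$derived_leaves)) {
    cat(sprintf("  focal site: %d derived leaves, mutation branch above node %d\n",
                length(x$derived_leaves),
                if (is.null(x$mutation_branch)) NA_integer_ else x$mutation_branch))
  }
  invisible(x)
}

#' Time to the most recent common ancestor
#'
#' @param g a [genealogy()].
#' @return The root height in generations.
#' @export
tmrca <- function(g) max(g$node_time)

#' Sorted coalescent times of a genealogy
#'
#' Returns the strictly increasing times `t_1 < ... < t_{n-1}` of the `n - 1`
#' coalescent events (leaves sit at `t_0 = 0`).
#'
#' @param g a [genealogy()].
#' @return Numeric vector of length `n - 1`.
#' @export
coalescent_times <- function(g) sort(g$node_time[(g$n + 1L):(2L * g$n - 1L)])

# Resolve exactly tied internal node times by adding k*eps in node-index
# order (eps = 1e-9 of tree height); the matrix encoding requires a strict
# ranking of coalescent events.
break_time_ties <- function(g) {
  idx <- (g$n + 1L):(2L * g$n - 1L)
  tt <- g$node_time[idx]
  if (anyDuplicated(tt)) {
    eps <- 1e-9 * max(tt)
    if (eps <= 0) stop("cannot tie-break a tree with zero height")
    o <- order(tt, idx)
    adj <- tt[o]
    for (k in seq_along(adj)[-1L]) {
      if (adj[k] <= adj[k - 1L]) adj[k] <- adj[k - 1L] + eps
    }
    g$node_time[idx[o]] <- adj
  }
  g
}

#' Validate the structural invariants of a genealogy
#'
#' Checks that the tree is strictly binary, ultrametric (all leaves at time
#' 0, internal times positive and strictly ranked), connected with a single
#' root, and that `derived_leaves`, when present, is a proper non-empty
#' subset of the leaves forming a clade consistent with `mutation_branch`.
#'
#' @param g a [genealogy()].
#' @return `g`, invisibly; errors describe the violated invariant.
#' @export
validate_genealogy <- function(g) {
  n <- g$n
  m <- 2L * n - 1L
  if (sum(is.na(g$parent)) != 1L) stop("structural error: tree must have exactly one root")
  root <- which(is.na(g$parent))
  if (root <= n) stop("structural error: the root must be an internal node")
  kids <- tabulate(g$parent[!is.na(g$parent)], nbins = m)
  if (any(kids[1:n] != 0L)) stop("structural error: leaves cannot have children")
  internal <- (n + 1L):m
  if (any(kids[internal] != 2L)) {
    stop("structural error: non-binary tree (every coalescent node needs exactly 2 children)")
  }
  if (any(g$node_time[1:n] != 0)) {
    stop("structural error: non-ultrametric input (all leaves must be sampled at time 0)")
  }
  if (any(g$node_time[internal] <= 0)) stop("structural error: internal node times must be positive")
  if (anyDuplicated(g$node_time[internal])) {
    stop("structural error: coalescent times not strictly ranked")
  }
  bad <- which(!is.na(g$parent) & g$node_time[g$parent] <= g$node_time)
  if (length(bad)) stop("structural error: a child node is at least as old as its parent")
  if (!is.null(g$derived_leaves)) {
    d <- g$derived_leaves
    if (length(d) == 0L || length(d) >= n || any(d < 1L | d > n)) {
      stop("encoding error: derived_leaves must be a proper, non-empty subset of the leaves")
    }
    mb <- if (is.null(g$mutation_branch)) derived_clade_stem(g) else g$mutation_branch
    clade <- sort(descendant_leaves(g, mb))
    if (!identical(clade, d)) {
      stop(sprintf(
        "encoding error: derived_leaves do not form the clade below the mutation branch (offending leaves: %s)",
        paste(union(setdiff(clade, d), setdiff(d, clade)), collapse = ", ")))
    }
  }
  invisible(g)
}

# Leaves descending from (and including, if a leaf) node v.
descendant_leaves <- function(g, v) {
  if (v <= g$n) return(v)
  m <- 2L * g$n - 1L
  keep <- logical(m)
  keep[v] <- TRUE
  # node_time ordering is not a topological order for arbitrary indices, so
  # sweep by decreasing time: parents are always older than children.
  ord <- order(g$node_time, decreasing = TRUE)
  for (u in ord) {
    p <- g$parent[u]
    if (!is.na(p) && keep[p]) keep[u] <- TRUE
  }
  which(keep[1:g$n])
}

# Children lookup as a list indexed by node.
children_list <- function(g) {
  m <- 2L * g$n - 1L
  ch <- vector("list", m)
  for (v in seq_len(m)) {
    p <- g$parent[v]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# Stem node of the minimal clade containing exactly derived_leaves (their
# MRCA); errors if the derived set is not monophyletic.
derived_clade_stem <- function(g) {
  d <- g$derived_leaves
  if (length(d) == 1L) return(d)
  anc <- function(v) {
    out <- v
    while (!is.na(g$parent[v])) { v <- g$parent[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(d, anc))
  mrca <- common[which.min(g$node_time[common])]
  below <- sort(descendant_leaves(g, mrca))
  if (!identical(below, d)) {
    stop(sprintf(
      "encoding error: derived leaves are not monophyletic (clade of their MRCA also contains: %s)",
      paste(setdiff(below, d), collapse = ", ")))
  }
  mrca
}

# Nodes whose stem branch carries the derived allele: the mutation branch
# itself plus every branch inside its subtended clade.
derived_branch_nodes <- function(g) {
  mb <- g$mutation_branch
  if (is.null(mb)) mb <- derived_clade_stem(g)
  m <- 2L * g$n - 1L
  keep <- logical(m)
  keep[mb] <- TRUE
  ord <- order(g$node_time, decreasing = TRUE)
  for (u in ord) {
    p <- g$parent[u]
    if (!is.na(p) && keep[p]) keep[u] <- TRUE
  }
  which(keep)
}

#' Convert an ape phylogeny to a genealogy
#'
#' @param phy an [ape::phylo] object with branch lengths in generations;
#'   must be rooted, binary and ultrametric up to `tol`.
#' @param derived_leaves optional character or integer vector of derived tips
#'   (tip labels or tip indices).
#' @param tol relative tolerance for the ultrametricity check.
#' @return A [genealogy()].
#' @export
genealogy_from_phylo <- function(phy, derived_leaves = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  if (!ape::is.binary(phy)) stop("structural error: non-binary tree")
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  h <- max(depth[seq_len(n)])
  if (any(abs(depth[seq_len(n)] - h) > tol * h)) {
    stop("structural error: non-ultrametric input tree")
  }
  time <- h - depth
  time[seq_len(n)] <- 0
  parent <- rep(NA_integer_, 2L * n - 1L)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  if (is.character(derived_leaves)) {
    derived_leaves <- match(derived_leaves, phy$tip.label)
    if (anyNA(derived_leaves)) stop("unknown tip label in derived_leaves")
  }
  genealogy(parent, time, derived_leaves = derived_leaves)
}

#' Convert a genealogy to an ape phylogeny
#'
#' @param g a [genealogy()].
#' @return An [ape::phylo] object with tip labels `t1..tn` and branch lengths
#'   in generations.
#' @export
genealogy_to_phylo <- function(g) {
  n <- g$n
  m <- 2L * n - 1L
  # ape wants the root to be node n+1 and internal nodes n+1..2n-1.
  root <- which(is.na(g$parent))
  internal <- (n + 1L):m
  relab <- seq_len(m)
  others <- setdiff(internal, root)
  relab[root] <- n + 1L
  relab[others] <- setdiff(internal, n + 1L)
  child <- which(!is.na(g$parent))
  edge <- cbind(relab[g$parent[child]], relab[child])
  phy <- list(edge = edge,
              edge.length = g$node_time[g$parent[child]] - g$node_time[child],
              tip.label = paste0("t", seq_len(n)),
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a random neutral coalescent genealogy
#'
#' Draws a ranked topology by uniform random pairwise merging and coalescent
#' waiting times under a (possibly non-equilibrium) demographic model. Used
#' both as a data generator and as the randomized test harness for the
#' matrix encoding.
#'
#' @param n leaf count (>= 2).
#' @param demography a [demography_model()]; default is equilibrium
#'   `Ne = 10000`.
#' @param derived optional: `"random"` to mark a uniformly chosen non-root
#'   clade as derived, or `NULL` for no focal site.
#' @return A [genealogy()].
#' @export
random_genealogy <- function(n, demography = demography_model(0, 1e4),
                             derived = NULL) {
  st <- sim_coalescent_tree(n, demography)
  dl <- NULL
  mb <- NULL
  if (!is.null(derived) && identical(derived, "random")) {
    # any node except the root subtends a proper leaf subset
    mb <- sample(setdiff(seq_len(2L * n - 1L), which(is.na(st$parent))), 1L)
  }
  g <- genealogy(st$parent, st$node_time, validate = FALSE)
  if (!is.null(mb)) {
    g$mutation_branch <- mb
    g$derived_leaves <- sort(descendant_leaves(g, mb))
  }
  validate_genealogy(g)
  g
}
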