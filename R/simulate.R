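#' @title Coalescent simulation of genomic regions
#' @description Internal machinery: a single-tree coalescent under
#'   piecewise-constant demography, and a sequentially Markov coalescent
#'   (SMC) along the sequence for recombination. Lineage pairs coalesce at
#'   rate `1/(2 Ne(t))`; the SMC recombination step detaches the lineage
#'   above a uniformly chosen point on the current tree and re-coalesces it
#'   with the remaining branches, which leaves the marginal tree at every
#'   position distributed as the standard coalescent.
#' @name coalescent-simulator
NULL

# Single neutral coalescent tree: returns parent / node_time vectors
# (leaves 1..n at time 0, internal nodes n+1 .. 2n-1 in merge order).
sim_coalescent_tree <- function(n, demography) {
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  node_time <- numeric(m)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- pw_coal_time(demography, t, k * (k - 1) / 2)
    pair <- sample(k, 2L)
    parent[active[pair]] <- nxt
    node_time[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, node_time = node_time)
}

total_branch_length <- function(parent, node_time) {
  ch <- which(!is.na(parent))
  sum(node_time[parent[ch]] - node_time[ch])
}

# Descendant leaves of node v given a time-decreasing node ordering.
desc_leaves_raw <- function(parent, n, v, ord) {
  m <- length(parent)
  if (v <= n) return(v)
  keep <- logical(m)
  keep[v] <- TRUE
  for (u in ord) {
    p <- parent[u]
    if (!is.na(p) && keep[p]) keep[u] <- TRUE
  }
  which(keep[1:n])
}

# One SMC recombination update of (parent, node_time). Returns the new tree.
smc_recombine <- function(parent, node_time, demography) {
  ch <- which(!is.na(parent))
  blen <- node_time[parent[ch]] - node_time[ch]
  b <- ch[sample.int(length(ch), 1L, prob = blen)]
  u <- stats::runif(1L, node_time[b], node_time[parent[b]])
  # prune the lineage above u: splice out b's parent p
  p <- parent[b]
  sib <- setdiff(which(!is.na(parent) & parent == p), b)
  gp <- parent[p]
  parent[sib] <- gp                      # NA if p was the root
  parent[b] <- NA_integer_
  parent[p] <- NA_integer_
  root <- if (is.na(gp)) sib else {
    r <- gp
    while (!is.na(parent[r])) r <- parent[r]
    r
  }
  # re-coalesce the floating lineage from time u upward; lineage count in
  # the pruned tree changes at its node times, plus one root lineage above
  # the pruned TMRCA
  act <- setdiff(which(!is.na(parent)), b)
  t_lo <- node_time[act]
  t_hi <- node_time[parent[act]]
  t_root <- node_time[root]
  brk <- sort(unique(c(u, t_lo[t_lo > u], t_hi[t_hi > u], t_root[t_root > u])))
  t_star <- NA_real_
  for (s in seq_along(brk)) {
    s0 <- brk[s]
    s1 <- if (s < length(brk)) brk[s + 1L] else Inf
    mid <- if (is.finite(s1)) (s0 + s1) / 2 else s0 + 1
    k <- sum(t_lo <= mid & t_hi > mid) + (mid >= t_root)
    tc <- pw_coal_time(demography, s0, k)
    if (tc < s1) { t_star <- tc; break }
  }
  # choose uniformly among lineages alive at t_star
  alive <- act[t_lo <= t_star & t_hi > t_star]
  cand <- if (t_star >= t_root) c(alive, root) else alive
  cc <- cand[sample.int(length(cand), 1L)]
  node_time[p] <- t_star
  if (cc == root && t_star >= t_root) {
    parent[root] <- p
    parent[b] <- p
  } else {
    parent[p] <- parent[cc]
    parent[cc] <- p
    parent[b] <- p
  }
  list(parent = parent, node_time = node_time)
}

# Neutral region under the SMC: tree intervals plus (optionally) mutations.
sim_region <- function(n, L, mu, rho, demography, genotypes = TRUE) {
  tr <- sim_coalescent_tree(n, demography)
  intervals <- NULL
  trees <- list()
  x <- 0
  repeat {
    lambda <- total_branch_length(tr$parent, tr$node_time)
    dx <- if (rho > 0) stats::rexp(1L, rho * lambda) else Inf
    xe <- min(x + dx, L)
    trees[[length(trees) + 1L]] <- tr
    intervals <- rbind(intervals, c(x, xe))
    if (x + dx >= L) break
    x <- xe
    tr <- smc_recombine(tr$parent, tr$node_time, demography)
  }
  reg <- list(n = n, L = L, mu = mu, rho = rho,
              demography = demography$label,
              intervals = intervals, trees = trees)
  if (genotypes) reg <- c(reg, drop_mutations(reg)) else {
    tl <- vapply(trees, function(t) total_branch_length(t$parent, t$node_time),
                 numeric(1))
    reg$n_sites <- stats::rpois(1L, mu * sum((intervals[, 2] - intervals[, 1]) * tl))
  }
  structure(reg, class = "region_sim")
}

# Poisson mutation drop over the recorded trees of a region.
drop_mutations <- function(reg) {
  pos <- numeric(0)
  cols <- list()
  n <- reg$n
  for (i in seq_along(reg$trees)) {
    tr <- reg$trees[[i]]
    ch <- which(!is.na(tr$parent))
    blen <- tr$node_time[tr$parent[ch]] - tr$node_time[ch]
    lambda <- sum(blen)
    a <- reg$intervals[i, 1]; b <- reg$intervals[i, 2]
    nm <- stats::rpois(1L, reg$mu * (b - a) * lambda)
    if (nm == 0L) next
    ord <- order(tr$node_time, decreasing = TRUE)
    nodes <- ch[sample.int(length(ch), nm, replace = TRUE, prob = blen)]
    for (v in nodes) {
      carriers <- desc_leaves_raw(tr$parent, n, v, ord)
      if (length(carriers) == 0L || length(carriers) == n) next
      col <- integer(n); col[carriers] <- 1L
      cols[[length(cols) + 1L]] <- col
      pos <- c(pos, stats::runif(1L, a, b))
    }
  }
  if (length(cols)) {
    o <- order(pos)
    list(genotypes = do.call(rbind, cols)[o, , drop = FALSE],
         positions = pos[o], n_sites = length(pos))
  } else {
    list(genotypes = matrix(integer(0), 0L, reg$n), positions = numeric(0),
         n_sites = 0L)
  }
}

#' @export
print.region_sim <- function(x, ...) {
  cat(sprintf("<region_sim> %d samples, %g bp, %d marginal trees, %s segregating sites\n",
              x$n, x$L, length(x$trees),
              if (is.null(x$n_sites)) "un-dropped" else as.character(x$n_sites)))
  invisible(x)
}

#' Simulate a genomic region
#'
#' The user-facing simulation entry point: a neutral region under the
#' sequentially Markov coalescent, or a region containing a hard/soft
#' selective sweep. Sweep regions are simulated window-by-window with a
#' structured coalescent conditioned on a deterministic logistic frequency
#' trajectory of the beneficial allele; lineages linked to the sweep escape
#' it by recombination with probability `1 - exp(-(rho d / s) log(2 Ne s))`
#' at distance `d` from the selected site, which produces the classic valley
#' of diversity around the sweep.
#'
#' @param demography a [demography_model()].
#' @param L region length in bp (0-based, half-open coordinates).
#' @param mu,rho per-bp per-generation mutation and recombination rates.
#' @param n_samples number of haploid samples.
#' @param sweep `NULL` for neutral, or a [sweep_params()].
#' @param seed optional integer seed (full reproducibility).
#' @param genotypes drop mutations and return the genotype matrix
#'   (`n_sites x n_samples`, 0 = ancestral / 1 = derived) with positions.
#' @return A `region_sim` object: marginal trees with half-open intervals,
#'   genotypes/positions when requested, and for sweep simulations the focal
#'   site metadata.
#' @examples
#' \donttest{
#' eq <- demography_model(0, 1e4)
#' reg <- simulate_region(eq, L = 1e4, mu = 1.25e-8, rho = 1.25e-8,
#'                        n_samples = 10, seed = 1)
#' reg$n_sites
#' }
#' @export
simulate_region <- function(demography, L, mu, rho, n_samples, sweep = NULL,
                            seed = NULL, genotypes = TRUE) {
  stopifnot(L > 0, mu >= 0, rho >= 0, n_samples >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sweep)) {
    sim_region(n_samples, L, mu, rho, demography, genotypes = genotypes)
  } else {
    sweep_region(n_samples, L, mu, rho, demography, sweep)
  }
}

#' Sweep simulation parameters
#'
#' @param s selection coefficient of the beneficial allele (> 0; genic
#'   selection, i.e. dominance 0.5, unless `h` is set).
#' @param f_init initial frequency for a soft sweep from standing variation
#'   (0 for a hard sweep from a new mutation).
#' @param sweep_position position of the selected site in bp; defaults to
#'   the central nucleotide `floor(L/2)` when used by [simulate_region()].
#' @param h dominance coefficient (recorded; the trajectory uses genic
#'   selection).
#' @param condition sampling condition: `"segregating"` draws the present-day
#'   frequency of the beneficial allele uniformly from `freq_range`;
#'   `"frequency"` uses `freq` exactly.
#' @param freq present-day frequency for `condition = "frequency"`.
#' @param freq_range range for `condition = "segregating"`.
#' @return An object of class `"sweep_params"`.
#' @export
sweep_params <- function(s, f_init = 0, sweep_position = NULL, h = 0.5,
                         condition = c("segregating", "frequency"),
                         freq = NULL, freq_range = c(0.05, 0.95)) {
  stopifnot(s > 0, f_init >= 0, f_init < 1)
  condition <- match.arg(condition)
  structure(list(s = s, f_init = f_init, sweep_position = sweep_position,
                 h = h, condition = condition, freq = freq,
                 freq_range = freq_range),
            class = "sweep_params")
}

# Structured coalescent at (or linked to) a sweeping site, conditioned on a
# deterministic logistic trajectory run backward in discrete generations.
# `derived` flags which of the n leaves carry the beneficial allele;
# `escaped` flags derived leaves that recombined off the sweep (treated as
# ancestral-class from the start). Returns parent/node_time plus the node
# whose stem branch carries the beneficial mutation (origin lineage).
sweep_structured_tree <- function(n, demography, s, x0, f_init, derived,
                                  escaped = rep(FALSE, n)) {
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  node_time <- numeric(m)
  nxt <- n + 1L
  lineage <- seq_len(n)
  cls <- derived & !escaped            # TRUE = sweep class
  x <- x0
  tau <- 0
  es <- exp(s)
  origin_node <- NA_integer_
  merge <- function(ids, tt) {
    parent[ids] <<- nxt
    node_time[nxt] <<- tt
    nxt <<- nxt + 1L
    nxt - 1L
  }
  soft <- f_init > 0
  repeat {
    kd <- sum(cls)
    Ne <- ne_at(demography, tau)
    if (!soft && x <= 1 / (2 * Ne) && kd >= 1L) {
      # origin of the hard sweep: all remaining sweep-class lineages
      # coalesce into the mutation lineage
      while (sum(cls) > 1L) {
        ids <- which(cls)
        pick <- ids[sample.int(length(ids), 2L)]
        nn <- merge(lineage[pick], tau)
        lineage <- c(lineage[-pick], nn)
        cls <- c(cls[-pick], TRUE)
      }
      origin_node <- lineage[which(cls)]
      cls[] <- FALSE
      break
    }
    if (soft && x <= f_init) {
      x <- f_init  # standing phase: frequency held at f_init
      if (kd <= 1L) {
        if (kd == 1L) origin_node <- lineage[which(cls)]
        cls[] <- FALSE
        break
      }
    }
    if (kd == 0L) break
    tau <- tau + 1
    # one generation back: within-class coalescence
    for (side in c(TRUE, FALSE)) {
      repeat {
        ids <- which(cls == side)
        k <- length(ids)
        freq <- if (side) x else 1 - x
        pr <- if (k >= 2L) k * (k - 1) / 2 / (2 * Ne * max(freq, 1e-12)) else 0
        if (pr <= 0 || stats::runif(1L) > min(pr, 1)) break
        pick <- ids[sample.int(k, 2L)]
        nn <- merge(lineage[pick], tau)
        lineage <- c(lineage[-pick], nn)
        cls <- c(cls[-pick], side)
      }
    }
    if (x > f_init || !soft) x <- x / (es * (1 - x) + x)
    if (tau > 5e5) stop("simulation error: sweep phase failed to resolve")
  }
  # neutral continuation for all remaining lineages
  while (length(lineage) > 1L) {
    k <- length(lineage)
    tau <- pw_coal_time(demography, tau, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    nn <- merge(lineage[pick], tau)
    lineage <- lineage[-pick]
    cls <- cls[-pick]
    lineage <- c(lineage, nn)
    cls <- c(cls, FALSE)
  }
  list(parent = parent, node_time = node_time, origin_node = origin_node)
}

#' Simulate the genealogy at a sweeping focal site
#'
#' Runs the structured coalescent at the selected site itself (no escape by
#' recombination), conditioned on a deterministic logistic trajectory of the
#' beneficial allele, and returns a [genealogy()] whose focal mutation
#' branch is the sweep's origin lineage.
#'
#' @param n haploid sample size.
#' @param demography a [demography_model()].
#' @param sweep a [sweep_params()].
#' @param max_tries resampling cap for drawing a derived-leaf count strictly
#'   between 0 and n.
#' @return A [genealogy()] with `derived_leaves` and `mutation_branch` set.
#' @export
sweep_genealogy <- function(n, demography, sweep, max_tries = 100L) {
  x0 <- switch(sweep$condition,
               segregating = stats::runif(1L, sweep$freq_range[1], sweep$freq_range[2]),
               frequency = sweep$freq)
  if (is.null(x0) || x0 <= 0 || x0 >= 1) {
    stop("sweep sampling condition must give a present-day frequency in (0, 1)")
  }
  for (i in seq_len(max_tries)) {
    nd <- stats::rbinom(1L, n, x0)
    if (nd > 0L && nd < n) break
    if (i == max_tries) stop("simulation error: could not draw a segregating derived count")
  }
  derived <- logical(n)
  derived[sample.int(n, nd)] <- TRUE
  st <- sweep_structured_tree(n, demography, sweep$s, x0, sweep$f_init, derived)
  g <- genealogy(st$parent, st$node_time, validate = FALSE)
  g$mutation_branch <- st$origin_node
  g$derived_leaves <- sort(descendant_leaves(g, st$origin_node))
  validate_genealogy(g)
  g
}

#' Simulate a neutral genealogy with a random focal mutation
#'
#' The neutral-class counterpart of [sweep_genealogy()]: a standard
#' coalescent tree under `demography` with the focal mutation placed on a
#' branch drawn proportionally to branch length, so that derived-allele
#' frequencies follow the neutral site-frequency spectrum.
#'
#' @inheritParams sweep_genealogy
#' @return A [genealogy()] with a focal site.
#' @export
neutral_focal_genealogy <- function(n, demography) {
  tr <- sim_coalescent_tree(n, demography)
  g <- genealogy(tr$parent, tr$node_time, validate = FALSE)
  ch <- which(!is.na(g$parent))
  blen <- g$node_time[g$parent[ch]] - g$node_time[ch]
  g$mutation_branch <- ch[sample.int(length(ch), 1L, prob = blen)]
  g$derived_leaves <- sort(descendant_leaves(g, g$mutation_branch))
  validate_genealogy(g)
  g
}

# Window-wise sweep region: shared derived set at the focal site, with
# per-window escape by recombination, then Poisson mutation drop.
sweep_region <- function(n, L, mu, rho, demography, sweep, window = 2000) {
  pos0 <- if (is.null(sweep$sweep_position)) floor(L / 2) else sweep$sweep_position
  stopifnot(pos0 >= 0, pos0 < L)
  x0 <- switch(sweep$condition,
               segregating = stats::runif(1L, sweep$freq_range[1], sweep$freq_range[2]),
               frequency = sweep$freq)
  nd <- 0L
  while (nd == 0L || nd == n) nd <- stats::rbinom(1L, n, x0)
  derived <- logical(n)
  derived[sample.int(n, nd)] <- TRUE
  Ne0 <- ne_at(demography, 0)
  starts <- seq(0, L, by = window)
  if (starts[length(starts)] >= L) starts <- starts[-length(starts)]
  trees <- list()
  intervals <- NULL
  pos <- numeric(0)
  cols <- list()
  focal_tree_idx <- NA_integer_
  for (w in seq_along(starts)) {
    a <- starts[w]; b <- min(a + window, L)
    d <- abs((a + b) / 2 - pos0)
    contains_focal <- pos0 >= a && pos0 < b
    if (contains_focal) d <- 0
    p_esc <- 1 - exp(-(rho * d / sweep$s) * log(max(2 * Ne0 * sweep$s, exp(1))))
    escaped <- derived & (stats::runif(n) < p_esc)
    st <- sweep_structured_tree(n, demography, sweep$s, x0, sweep$f_init,
                                derived, escaped)
    trees[[w]] <- st[c("parent", "node_time")]
    intervals <- rbind(intervals, c(a, b))
    if (contains_focal) focal_tree_idx <- w
    ch <- which(!is.na(st$parent))
    blen <- st$node_time[st$parent[ch]] - st$node_time[ch]
    nm <- stats::rpois(1L, mu * (b - a) * sum(blen))
    if (nm > 0L) {
      ord <- order(st$node_time, decreasing = TRUE)
      nodes <- ch[sample.int(length(ch), nm, replace = TRUE, prob = blen)]
      for (v in nodes) {
        carriers <- desc_leaves_raw(st$parent, n, v, ord)
        if (length(carriers) == 0L || length(carriers) == n) next
        col <- integer(n); col[carriers] <- 1L
        cols[[length(cols) + 1L]] <- col
        pos <- c(pos, stats::runif(1L, a, b))
      }
    }
  }
  # the selected site itself
  col <- integer(n); col[derived] <- 1L
  cols[[length(cols) + 1L]] <- col
  pos <- c(pos, pos0)
  o <- order(pos)
  structure(list(n = n, L = L, mu = mu, rho = rho,
                 demography = demography$label,
                 intervals = intervals, trees = trees,
                 genotypes = do.call(rbind, cols)[o, , drop = FALSE],
                 positions = pos[o], n_sites = length(pos),
                 sweep = sweep, focal_position = pos0,
                 focal_tree = focal_tree_idx,
                 derived_leaves = which(derived)),
            class = "region_sim")
}

#' Extract the marginal genealogy at a focal position
#'
#' Looks up the marginal tree whose half-open interval `[start, end)`
#' contains `focal_position` and attaches the derived-leaf set from the
#' biallelic variant at the focal site, when one exists.
#'
#' @param region a `region_sim` from [simulate_region()].
#' @param focal_position position in bp.
#' @param focal_site_required error if no biallelic variant sits at the
#'   focal position (within 0.5 bp).
#' @return A [genealogy()].
#' @export
extract_focal_genealogy <- function(region, focal_position,
                                    focal_site_required = FALSE) {
  stopifnot(inherits(region, "region_sim"))
  if (focal_position < 0 || focal_position >= region$L) {
    stop("range error: focal_position outside the simulated sequence")
  }
  idx <- which(region$intervals[, 1] <= focal_position &
                 focal_position < region$intervals[, 2])[1L]
  tr <- region$trees[[idx]]
  dl <- NULL
  if (!is.null(region$positions) && length(region$positions)) {
    hit <- which(abs(region$positions - focal_position) < 0.5)
    if (length(hit)) {
      counts <- rowSums(region$genotypes[hit, , drop = FALSE])
      hit <- hit[counts > 0L & counts < region$n]
      if (length(hit)) dl <- which(region$genotypes[hit[1L], ] == 1L)
    }
  }
  if (is.null(dl) && focal_site_required) {
    stop("data error: no biallelic segregating site at the focal position")
  }
  genealogy(tr$parent, tr$node_time, derived_leaves = dl)
}

#' Simulate one recombination-rate training example
#'
#' One labeled example for the recombination-rate regression task: `n`
#' haploid samples over an `L`-bp region with the mutation rate and the
#' recombination rate each drawn uniformly per example; the label is the
#' drawn `rho`. Regions with zero segregating sites are kept and flagged
#' (empty genotype matrix).
#'
#' @param demography a [demography_model()].
#' @param n haploid sample size (32 in the reference experiments).
#' @param L region length in bp (300 kb in the reference experiments).
#' @param mu_range,rho_range uniform sampling ranges for the per-bp rates.
#' @param seed optional integer seed.
#' @return A list: `genotypes` (`n_sites x n`), `positions` (bp), `mu`,
#'   `rho` (the label), `n_sites`.
#' @export
simulate_relernn_example <- function(demography, n = 32L, L = 3e5,
                                     mu_range = c(1.875e-8, 3.125e-8),
                                     rho_range = c(0, 6.25e-8),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::runif(1L, mu_range[1], mu_range[2])
  rho <- stats::runif(1L, rho_range[1], rho_range[2])
  reg <- sim_region(n, L, mu, rho, demography, genotypes = TRUE)
  list(genotypes = reg$genotypes, positions = reg$positions,
       mu = mu, rho = rho, n_sites = reg$n_sites)
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_W = S / (a_n L)` per bp, with `a_n = sum_{k=1}^{n-1} 1/k`.
#'
#' @param S number of segregating sites.
#' @param n number of haploid samples (>= 2).
#' @param L sequence length in bp.
#' @return Per-bp Watterson theta.
#' @examples
#' watterson_theta(6, 4, 1)  # 6 / (1 + 1/2 + 1/3) = 3.2727...
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("domain error: Watterson's estimator needs n >= 2")
  stopifnot(L > 0, S >= 0)
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Equilibrium effective size implied by Watterson's theta
#'
#' `Ne = theta_W / (4 mu)`: the constant population size whose neutral
#' diversity matches the observed per-bp Watterson estimator.
#'
#' @param theta_w per-bp Watterson theta.
#' @param mu per-bp per-generation mutation rate (> 0).
#' @return Effective population size.
#' @export
equilibrium_ne <- function(theta_w, mu) {
  if (mu <= 0) stop("domain error: mu must be positive")
  theta_w / (4 * mu)
}

#' Background-selection configuration
#'
#' Describes purifying selection acting on a central "genic" span, with a
#' gamma distribution of fitness effects. In `surrogate` mode (the built-in
#' desk-scale stand-in for forward simulation) its only effect on the
#' coalescent is a region-wide diversity-reduction factor `B` in `(0, 1]`
#' applied to `Ne`; `external` mode expects forward-simulated tree input via
#' the ingest adapter.
#'
#' @param genic_span `(start, end)` bp of the constrained region.
#' @param dfe_mean mean selection coefficient of deleterious mutations
#'   (negative; default -0.03).
#' @param dfe_shape gamma shape of the DFE (default 0.2).
#' @param h dominance coefficient of deleterious mutations (default 0.25).
#' @param mode `"surrogate"` or `"external"`.
#' @param B optional fixed diversity-reduction factor; when `NULL`,
#'   [apply_bgs_surrogate()] draws `B ~ U[0.7, 0.95]` per region.
#' @return An object of class `"bgs_config"`.
#' @export
bgs_config <- function(genic_span, dfe_mean = -0.03, dfe_shape = 0.2,
                       h = 0.25, mode = c("surrogate", "external"), B = NULL) {
  stopifnot(dfe_mean < 0, dfe_shape > 0, h >= 0, h <= 1,
            length(genic_span) == 2L, genic_span[2] > genic_span[1])
  structure(list(genic_span = as.numeric(genic_span), dfe_mean = dfe_mean,
                 dfe_shape = dfe_shape, h = h, mode = match.arg(mode), B = B),
            class = "bgs_config")
}

#' Apply the background-selection surrogate to a simulation configuration
#'
#' Scales the demography by a diversity-reduction factor `B` (drawn from
#' `U[0.7, 0.95]` unless fixed in the config), emulating the reduction of
#' linked neutral diversity caused by purifying selection against mutations
#' from the configured DFE. The realized `B` is recorded for the manifest.
#'
#' @param config a [bgs_config()] with `mode = "surrogate"`.
#' @param demography the base [demography_model()].
#' @return A list: `demography` (scaled model) and `B` (realized factor).
#' @export
apply_bgs_surrogate <- function(config, demography) {
  stopifnot(inherits(config, "bgs_config"))
  if (config$mode != "surrogate") {
    stop("configuration error: external mode requires forward-simulated tree input via the ingest adapter")
  }
  B <- if (is.null(config$B)) stats::runif(1L, 0.7, 0.95) else config$B
  list(demography = scale_demography(demography, B), B = B)
}

#' Perturb a genealogy with an inference-error surrogate
#'
#' Emulates the distortions introduced by reconstructing genealogies from
#' sequence data: every branch length is multiplied by an independent
#' lognormal factor (`sdlog = sigma_bl`), node times are re-derived so the
#' tree stays ultrametric, and each internal edge is independently subjected
#' to a nearest-neighbor interchange with probability `p_nni` (skipped when
#' the move would make a child older than its parent). The derived-leaf set
#' is re-derived from the (retained) mutation branch after topology moves.
#'
#' @param g a [genealogy()].
#' @param sigma_bl lognormal branch-length noise (>= 0); 0 leaves lengths
#'   unchanged.
#' @param p_nni per-internal-edge topology-swap probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A perturbed [genealogy()] satisfying all structural invariants.
#' @export
apply_inference_error <- function(g, sigma_bl = 0.3, p_nni = 0.05, seed = NULL) {
  stopifnot(sigma_bl >= 0, p_nni >= 0, p_nni <= 1)
  validate_genealogy(g)
  if (!is.null(seed)) set.seed(seed)
  if (sigma_bl == 0 && p_nni == 0) return(g)
  n <- g$n
  m <- 2L * n - 1L
  parent <- g$parent
  time <- g$node_time
  if (sigma_bl > 0) {
    ch <- which(!is.na(parent))
    fac <- stats::rlnorm(length(ch), 0, sigma_bl)
    elen <- (time[parent[ch]] - time[ch]) * fac
    # depths from the root with perturbed lengths
    depth <- numeric(m)
    ord <- order(time, decreasing = TRUE)
    for (v in ord) {
      p <- parent[v]
      if (!is.na(p)) depth[v] <- depth[p] + elen[match(v, ch)]
    }
    H <- mean(depth[1:n])
    # per-node mean leaf depth below, for leaf-depth renormalization
    cnt <- numeric(m); acc <- numeric(m)
    cnt[1:n] <- 1; acc[1:n] <- depth[1:n]
    for (v in order(time)) {
      p <- parent[v]
      if (!is.na(p)) { cnt[p] <- cnt[p] + cnt[v]; acc[p] <- acc[p] + acc[v] }
    }
    newt <- H * (1 - depth / (acc / cnt))
    newt[1:n] <- 0
    # enforce parent > child where renormalization locally inverted an
    # edge, sweeping children before parents (original-time order is
    # topological)
    for (v in order(time[(n + 1L):m]) + n) {
      kids <- which(!is.na(parent) & parent == v)
      lim <- max(newt[kids])
      if (newt[v] <= lim) newt[v] <- lim + 1e-6 * H
    }
    time <- newt
  }
  if (p_nni > 0) {
    internal <- setdiff((n + 1L):m, which(is.na(parent)))
    for (v in internal) {
      if (stats::runif(1L) > p_nni) next
      p <- parent[v]
      sib <- setdiff(which(!is.na(parent) & parent == p), v)
      if (time[sib] >= time[v]) next  # swap would break the time order
      kids <- which(!is.na(parent) & parent == v)
      cmove <- kids[sample.int(2L, 1L)]
      parent[cmove] <- p
      parent[sib] <- v
    }
  }
  out <- genealogy(parent, time, validate = TRUE)
  if (!is.null(g$mutation_branch)) {
    out$mutation_branch <- g$mutation_branch
    out$derived_leaves <- sort(descendant_leaves(out, g$mutation_branch))
    if (length(out$derived_leaves) == n) {
      # root-spanning after a swap at the root edge: drop the focal site
      out$mutation_branch <- NULL
      out$derived_leaves <- NULL
    }
  }
  out
}
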