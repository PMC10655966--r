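#' Piecewise-constant demographic model
#'
#' A single-population demographic history given as piecewise-constant
#' effective sizes looking backward in time: epoch `i` spans
#' `[start_gen[i], start_gen[i+1])` generations before the present (the last
#' epoch extends to infinity) with diploid effective size `ne[i]`. A pair of
#' haploid lineages coalesces at rate `1 / (2 Ne)` per generation, so neutral
#' equilibrium nucleotide diversity is `4 Ne mu` per bp.
#'
#' @param start_gen numeric vector of epoch start times in generations,
#'   strictly increasing from 0.
#' @param ne positive effective sizes, one per epoch.
#' @param label free-text description.
#' @return An object of class `"demography_model"`.
#' @examples
#' eq <- demography_model(0, 1e4, "equilibrium Ne = 10,000")
#' bn <- demography_model(c(0, 1000, 2000), c(1e4, 500, 1e4), "5% bottleneck")
#' @export
demography_model <- function(start_gen, ne, label = "") {
  start_gen <- as.numeric(start_gen)
  ne <- as.numeric(ne)
  if (length(start_gen) != length(ne) || length(ne) < 1L) {
    stop("start_gen and ne must have equal positive length")
  }
  if (start_gen[1L] != 0 || is.unsorted(start_gen, strictly = TRUE)) {
    stop("epoch starts must increase strictly from 0")
  }
  if (any(ne <= 0)) stop("all Ne must be positive")
  structure(list(start_gen = start_gen, ne = ne, label = as.character(label)),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model> %s\n", if (nzchar(x$label)) x$label else "(unlabeled)"))
  print(data.frame(start_gen = x$start_gen, Ne = x$ne), row.names = FALSE)
  invisible(x)
}

#' Effective size at a time point
#'
#' @param demography a [demography_model()].
#' @param t time in generations before the present (vectorized).
#' @return `Ne` at each time.
#' @export
ne_at <- function(demography, t) {
  demography$ne[findInterval(t, demography$start_gen)]
}

#' Rescale a demography by a diversity-reduction factor
#'
#' Multiplies every epoch's `Ne` by `B`, the region-wide reduction factor
#' used by the background-selection surrogate.
#'
#' @param demography a [demography_model()].
#' @param B factor in `(0, 1]`.
#' @return A rescaled [demography_model()].
#' @export
scale_demography <- function(demography, B) {
  stopifnot(B > 0, B <= 1)
  demography_model(demography$start_gen, demography$ne * B,
                   label = sprintf("%s [x%.3g]", demography$label, B))
}

#' The packaged European demographic model
#'
#' A piecewise-constant single-population approximation of the European
#' (CEU) demographic history of Tennessen et al. (2012): an ancestral size of
#' 7,310 diploids, an ancient expansion to 14,474 at 5,920 generations before
#' present, an out-of-Africa bottleneck to 1,861 at 2,040 generations, a
#' second bottleneck to 1,032 at 920 generations followed by exponential
#' growth at 0.307%/generation, and accelerated growth at 1.95%/generation
#' over the most recent ~205 generations, reaching ~512,000 at present
#' (generation time 25 years). The two exponential-growth phases are
#' discretized into geometric-mean piecewise-constant steps; all numbers live
#' in the plain-text fixture `extdata/european_demography.tsv`, not in code.
#'
#' @return A [demography_model()].
#' @export
european_demography <- function() {
  path <- system.file("extdata", "european_demography.tsv", package = "popdann",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  demography_model(tab$start_gen, tab$ne, label = "European (CEU), Tennessen et al. 2012")
}

# Sample the waiting time to the next event for a process whose rate is
# rate_scale / (2 Ne(t)) with piecewise-constant Ne, starting at time t0,
# optionally with additional rate-change breakpoints `extra_breaks` at which
# `rate_scale` changes (values `scales`, one per segment of the combined
# grid). Returns Inf if the total integrated rate is finite and exhausted.
pw_coal_time <- function(demography, t0, rate_scale) {
  if (rate_scale <= 0) return(Inf)
  target <- stats::rexp(1L)
  starts <- demography$start_gen
  nes <- demography$ne
  K <- length(starts)
  i <- findInterval(t0, starts)
  t <- t0
  repeat {
    rate <- rate_scale / (2 * nes[i])
    seg_end <- if (i < K) starts[i + 1L] else Inf
    span <- seg_end - t
    if (is.finite(span) && rate * span < target) {
      target <- target - rate * span
      t <- seg_end
      i <- i + 1L
    } else {
      return(t + target / rate)
    }
  }
}
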