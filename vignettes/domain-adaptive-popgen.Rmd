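---
title: "Domain-adaptive networks for simulation-trained population genetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-adaptive networks for simulation-trained population genetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Supervised machine-learning methods for population genetics are trained on
coalescent simulations, because simulations provide unlimited, perfectly
labeled examples of quantities — selection coefficients, recombination
rates, sweep status — that can never be observed directly in real data.
The approach inherits a structural weakness: the trained model is only as
good as the match between the simulator's assumptions and the process that
generated the real data. When the demographic model is wrong, when
background selection is present but unmodeled, or when the model consumes
*inferred* genealogies whose reconstruction errors the simulator never
produced, accuracy degrades — sometimes catastrophically — and this
*simulation mis-specification* is invisible to the usual benchmark of
testing on held-out simulations.

`popdann` treats the mismatch as an *unsupervised domain adaptation*
problem. The simulations are the labeled **source domain**; the real (or
differently simulated) data are the unlabeled **target domain**. A domain
classifier attached to the network's feature extractor through a
**gradient reversal layer** (GRL) is trained to distinguish the two
domains; because the GRL negates the gradient flowing back into the
feature extractor, the extractor is driven *away* from any representation
that separates them. Labels are never needed in the target domain; a held
back labeled target test set is used only to measure how well the scheme
worked.

## The genealogy encoding

For the selection tasks, the input is the genealogy at a focal site: a
ranked, binary, ultrametric coalescent tree of `n` contemporaneous haploid
samples with coalescent times `0 = t0 < t1 < ... < t_{n-1}`. Three
`(n-1) x (n-1)` lower-triangular matrices encode it, with row/column 1 the
most ancient inter-coalescent window:

* `W[i, j] = t_{n-j} - t_{n-1-i}` — the time span between the two
  coalescent events bounding the window, in generations. The reversed
  diagonal of `W` recovers every coalescent time by cumulative summation.
* `F[i, j]` — the number of branches whose closed lifespan
  `[child_time, parent_time]` contains the entire window. On the diagonal
  `F[k, k] = k + 1` exactly.
* `R[i, j]` — the same count restricted to branches carrying the derived
  allele at the focal site: the branch on which the mutation occurred plus
  every branch of the clade it subtends.

`F` is a bijective encoding of the ranked tree shape. `decode_F()` inverts
it for `n <= 7` by exhaustive search over all ranked shapes, deliberately
brute-force so the bijectivity claim is *verified* rather than assumed; the
test suite round-trips every ranked shape up to `n = 6`. Stacked, the three
channels form an `(n-1) x (n-1) x 3` image (`127 x 127 x 3` at the
reference sample size of 128 taxa), which is what the convolutional
feature extractor consumes.

Two conventions needed fixing where the window arithmetic alone does not
decide them. Containment is *closed*: a branch born or dying exactly at a
window endpoint counts, which is what makes the diagonal identity exact.
And `R` counts the mutation-carrying stem branch itself in addition to the
clade below it, keeping `R <= F` elementwise tight. Exactly tied
coalescent times (possible in trees ingested from discrete-generation
simulators) are resolved by adding `k * eps` (`eps` = 1e-9 of tree height)
in node-index order before ranking.

## The built-in simulator

No external simulator is required; all training and test data are generated
internally.

**Neutral coalescent with recombination.** Single trees are drawn under a
piecewise-constant demography (pair coalescence rate `1/(2 Ne(t))`).
Regions are extended along the sequence with the sequentially Markov
coalescent: recombination breakpoints arrive at rate `rho x` (total branch
length), and at each breakpoint the lineage above a uniformly chosen point
is detached and re-coalesced with the remaining branches under the same
demography. The marginal tree at every position remains exactly
coalescent-distributed; what the SMC approximates is only the correlation
structure between positions, which is the standard trade-off accepted by
ARG-based inference tools themselves. Mutations are dropped on each
marginal tree at rate `mu` per bp per generation.

**Demographies.** Any piecewise-constant single-population history. The
packaged European model (`european_demography()`) is a 25-epoch
discretization of the Tennessen et al. (2012) CEU history — ancestral size
7,310, ancient expansion to 14,474, out-of-Africa bottleneck at 1,861, a
second bottleneck at 1,032 followed by two exponential growth phases
reaching ~512,000 at present — with the growth phases discretized into
geometric-mean steps (10 and 12 epochs). Under this model, 32-sample
300-kb regions with `mu ~ U[1.875e-8, 3.125e-8]` yield a mean
Watterson-implied equilibrium size `theta_W / (4 mu)` of roughly 5,700 —
the quantity `scripts/acceptance.R` recomputes, and consistent with the
~6,000 used to calibrate the matched equilibrium source domain.

**Selective sweeps.** The genealogy at a sweeping site is drawn from a
structured coalescent conditioned on a deterministic logistic frequency
trajectory of the beneficial allele, run backward in discrete generations:
lineages carrying the derived allele coalesce at rate
`C(k,2) / (2 Ne x(t))`, non-carriers at the complementary rate, and at the
origin of a hard sweep the surviving derived lineages collapse into the
mutation lineage. Soft sweeps hold the trajectory at `f_init` during the
standing phase. Whole sweep regions are simulated window by window with
recombinational escape (`p_esc = 1 - exp(-(rho d / s) log(2 Ne s))` at
distance `d`), which reproduces the classic diversity valley; windows are
conditionally independent given the shared focal derived set, an
approximation that matters only for cross-window linkage, which the
genealogy tasks do not consume. The default sampling condition draws the
present-day beneficial-allele frequency uniformly from `[0.05, 0.95]`
rather than conditioning on fixation: at fixation the derived set is the
whole sample, the focal site is no longer segregating, and the derived
subtree channel `R` degenerates to `F` — the segregating condition is also
what real-data applications of ARG-based sweep inference use.

**Background selection surrogate.** Forward simulation of a deleterious
DFE is far outside a desk-scale budget, so `mode = "surrogate"` represents
background selection by its first-order population-genetic consequence: a
diversity-reduction factor `B ~ U[0.7, 0.95]` per region applied to `Ne`.
What the surrogate preserves is exactly what domain adaptation responds to
— a systematic distributional shift between source and target — and the
realized `B` is recorded in every manifest. Forward-simulated tree
sequences can be substituted through the ingest adapter
(`ingest_tree_sequence()`), which is also the route for trees produced by
ARG-inference tools.

**Genealogy-inference error surrogate.** Real applications never observe
true genealogies; they observe reconstructions. The surrogate multiplies
each branch length by an independent lognormal factor (`sigma_bl = 0.3`),
re-ultrametrizes by leaf-depth renormalization, and applies a
nearest-neighbor interchange to each internal edge with probability
`p_nni = 0.05` (skipped when the move would make a child older than its
parent). These defaults produce F/W distortions of the same qualitative
kind as ARG reconstruction error — mild topology shuffling plus
heteroskedastic time noise — without running an external inference tool;
both knobs are exposed, and the Frobenius distance of the encoded `F`
matrix from truth grows monotonically with `p_nni` (a property the test
suite checks).

## Networks and training

Every task network has three addressable components: a **feature
extractor**, a **label predictor**, and a **domain classifier** that
consumes the same feature vector through a GRL with weight `lambda = 1`
(equal weighting of the two losses; the weight is a config knob, constant
by default — no warm-up schedule). The standard model is the identical
network trained with the domain branch detached.

* Genealogy input: a convolutional stack (two 3x3 valid-padding ReLU
  blocks of 8 and 16 channels, each followed by 2x2 mean pooling, then
  global mean pooling) into a 16-unit ReLU feature layer.
* Genotype input: sites are recurrent steps; each step carries the `n`
  genotypes coded -1/+1, the normalized position, and the inter-site gap
  scaled by 50 so typical gaps are order one for the gates. A masked GRU
  (hidden 16) is mean-pooled over valid steps into the feature layer.
  Mean pooling rather than final-state readout is deliberate: the
  recombination signal (the local density of apparent breakpoints) is a
  per-site average, and at desk-scale training sizes a final-state readout
  memorizes idiosyncratic end-of-sequence patterns and generalizes
  measurably worse.
* Heads: an 8-unit ReLU layer into 2-way softmax (classification, domain)
  or a linear unit (regression). Regression targets are standardized —
  `log10(s)` for selection coefficients, units of 1e-8/bp for
  recombination rates — and back-transformed at prediction.

The exact layer dimensions of the full-scale reference architectures are
not published; these defaults are the package's own, sized so desk-scale
training fits a single CPU, and are recorded in `network_spec()` rather
than asserted as a reproduction. Parameter counts per component are
reported by `count_parameters()`.

Training uses Adam (learning rate 1e-3, batch size 64) with gradients
jointly rescaled to a global norm of at most 5 — backpropagation through a
hundred-plus recurrent steps occasionally explodes otherwise, and unclipped
runs at desk scale visibly diverge. Each domain-adaptive minibatch has two
components: 64 labeled source examples through the label predictor, and a
32 + 32 source/target mixture through the domain classifier (the mixture
fraction is a config knob; the reference description says only "a
mixture"). The source examples of the second component are the same pool
under an independent shuffle, drawn from an isolated RNG stream so that a
`lambda = 0` run consumes exactly the same batch permutations as standard
training and reproduces its trajectory bit for bit — the property that
pins down "the domain branch contributes nothing at `lambda = 0`" as a
testable statement. Back-propagation from the two components happens in
one combined update per step; the clipping norm is measured over the
feature-extractor and label-predictor gradients (the recurrent path the
clip guards) and the same factor rescales all components, which keeps a
`lambda = 0` domain-adaptive run bitwise identical to standard training.
An epoch is one pass over the labeled source pool; smaller target pools
are cycled with reshuffling (this is what a 10:1 source:target ratio
exercises). Early stopping monitors the *label predictor's* validation
loss only — never the domain loss — with patience 5 and restores the best
checkpoint; the domain classifier's validation loss is recorded per
epoch, since its trajectory (starting low and rising toward
`ln 2 ~ 0.693` under mis-specification; pinned near `ln 2` throughout
without) is itself diagnostic of how much domain shift the features
carried. One desk-scale caveat: in the first epoch or two of a run with
no domain shift, the adversarial game has not yet settled — Adam's
bias-corrected first steps are large and the GRL immediately counters the
domain head's noise fit — so the domain validation loss can transiently
overshoot `ln 2` by ~20% before pinning to chance for the rest of
training. A gradual `lambda` ramp (the warm-up schedule of the GRL's
originating method) suppresses this transient; it is available as a
config knob but disabled by default, since the constant equal-weight
scheme is this package's reference configuration.

## The benchmarking protocol

Four scenarios contextualize every experiment, all evaluated on the same
held-out target test set (the first on the matched source test set):

1. **source-matched** ("simulation benchmark"): train and test on source —
   how methods are usually benchmarked, and an optimistic bound.
2. **target-matched** ("hypothetical true model"): train on labeled target
   data — unobtainable in practice, the in-domain ceiling.
3. **standard**: train on source, apply to target — the workflow whose
   failure under mis-specification motivates everything else.
4. **domain-adaptive**: labeled source plus unlabeled target.

`run_misspec_suite()` sweeps severity — inference error only, bottlenecks
of 8,000/5,000/2,000/500 between generations 1,000 and 2,000, and an
extreme compound case (5% bottleneck, background selection, and target
`rho = 1e-7` against source 1.25e-8, an 8-fold mis-specification).
`run_imbalance_suite()` varies the sweep fraction of the unlabeled target
pool and the source:target size ratio, always evaluating on a balanced
test set. Metrics are AUPRC (step-integrated precision-recall, identical
to average precision), MAE, RMSE, mean signed error, and Welch's t on
per-example absolute errors for the standard-vs-adaptive comparison.

## Desk-scale problem sizes

The reference experiments train on 250,000–500,000 examples per domain at
128 taxa with GPU epochs of minutes; this package's defaults are sized for
a single CPU. The shipped configurations use 2,000–4,000 examples per
domain, 32 haploid samples, 30-kb regions for the recombination task, the
small networks above, and around 30 epochs — the scale at which every
qualitative claim (domain-adaptive improvement under mis-specification,
its absence without mis-specification, the downward bias of the standard
model under demographic mis-specification) is exercised by the test suite.
Validation splits are widened from the reference 2% to 5–10% at these
sizes: a 2% split of 2,000 examples is 40 regression examples, and
early-stopping on so noisy a signal restores near-random checkpoints.
Absolute desk-scale errors are necessarily far from the full-scale MAEs
(e.g. 5.45e-9 for the demography experiment); those numbers are registered
as full-scale targets, not desk checks.

## What the generator does and does not emulate

The synthetic domains reproduce the features the method responds to:
coalescent genealogy structure under arbitrary piecewise-constant
demography, hitchhiking at selected sites, diversity reduction from linked
purifying selection, reconstruction-like tree distortion, and controlled
gaps between source and target distributions. They do not contain
admixture or migration (single population only), gene conversion,
sequencing or phasing error, non-contemporaneous sampling, or real ARG
inference run on sequences; passing tests therefore demonstrate the
machinery and its directional behavior under the modeled shifts, not
performance on any real cohort. The `R` channel requires a biallelic,
segregating focal site by construction.

## Numerical choices, in one place

* Closed-interval branch-lifespan containment; `eps`-tie-breaking of
  coalescent times in node-index order.
* SMC re-coalescence rates evaluated on the merged grid of pruned-tree
  node times and demography epoch boundaries; the time-inhomogeneous
  waiting-time sampler walks epochs analytically (no discretization).
* Discrete-generation stepping for the sweep phase (at most one merger per
  class per generation, retried within a generation when rates exceed 1),
  continuous-time coalescent after sweep resolution.
* Glorot-normal initialization; Adam `beta1 = 0.9`, `beta2 = 0.999`,
  `eps = 1e-8`; global gradient-norm clip 5.
* Genotype-task padding length defaults to the 98th percentile of
  per-example site counts (longer examples keep an evenly spaced site
  subset) to bound recurrent sequence length against rare outliers.
* Zero-site regions are retained as flagged all-padding examples.
* Degenerate inputs rejected with typed errors: non-binary or
  non-ultrametric trees, non-clade derived sets, fixed or absent focal
  variants when required, empty target streams in domain-adaptive mode.

## Known limitations

Single-population demographies only; the three-population
demography-inference workflow that motivated one of the original SIA
experiments is out of scope (its role is covered by the bottleneck series
and the inference-error surrogate). The background-selection surrogate
captures diversity reduction but not the subtler distortions of the site
frequency spectrum that true forward simulation produces. Sweep-region
windows are conditionally independent given the focal derived set. The
desk-scale recombination regressor is a weak learner in absolute terms —
its purpose here is the domain-adaptation comparison, not
state-of-the-art rate estimation.
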