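---
title: "Time-stratified historical biogeography with fossil tips: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-stratified historical biogeography with fossil tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

paleorange reconstructs the geographic range evolution and latitudinal history
of a clade from a time-calibrated phylogeny that includes fossil tips. This
vignette is the package's own account of the models it implements, the choices
made where the methodology was genuinely open, and what the synthetic-data
tests do and do not establish.

## The geographic model

Ranges are sets of discrete areas, encoded as bitmasks. A time-stratified
model divides the tree's time span into geological slices, each with a
symmetric 0/1 connectivity matrix; a range is biologically plausible in a
slice only if its areas form a single connected component of that slice's
graph. We prune the state space to connected ranges of at most
`max_range_size` areas (default 5, matching the largest ancestral ranges one
meets in practice for the bundled cycad model); the global state space is the
union of the per-slice spaces plus the absorbing null (extinct) range.
Boundary times belong to the younger slice — a convention that makes slice
lookup right-continuous and avoids double counting.

The bundled `default_cycad_geo()` model has 14 areas (West/East Palearctic,
West/East Nearctic, Central America, Caribbean, South America, Africa,
Madagascar, India, Indonesia–Wallacea, Australasia, Greenland, Antarctica)
and four slices bounded at 358.9, 201.3, 66 and 23 Ma: Pangea assembly,
Gondwana/Laurasia, Paleogene, and Neogene-to-present. The adjacency matrices
are a coarse reading of standard paleogeographic reconstructions and are
fully user-overridable through `geo_model()` or a YAML config. The
high-latitude class used by event summaries defaults to
{WP, EP, WN, EN, GR, AN}; no canonical membership list exists for such
aggregates, so the mapping is an explicit, overridable argument.

## The DEC process

Anagenetic evolution is a continuous-time Markov chain: dispersal into area
*a* proceeds at rate *d* times the number of occupied areas adjacent to *a*
in the current slice (gains gated to ranges allowed in that slice), and each
occupied area is lost at rate *e*; a singleton losing its area enters the
absorbing null range. Losses whose target range is not in the global state
space (disconnected in every slice) have no state slot and are omitted.
Ranges disallowed in a slice keep their slot with an all-zero row: mass that
enters them in an earlier slice is frozen there until connectivity returns —
no remapping happens at slice boundaries.

At speciation the parent range is inherited by the canonical cladogenetic
distribution: a single-area parent is copied to both daughters; a wider
parent draws uniformly from subset sympatry (one daughter a single occupied
area, the other the full range; both orders) and vicariance (ordered splits
into two disjoint covering subsets with at least one side a single area).
Wide vicariance and founder-event jumps are deliberately absent.

The likelihood is Felsenstein pruning: branches are segmented at slice
boundaries, each segment propagated by `exp(Q_s dt)`; fossil tips simply end
above the present and enter the pruning at their age. Tip vectors implement
the two coding schemes: exact ranges, or presence-only coding for fossils
('?' in the range file) where every superset of the observed areas gets
likelihood 1. The root sums the partial likelihood over ranges allowed in the
root's slice with equal unit weight (the Lagrange convention; in the
zero-rate limit with identical singleton tips this gives log-likelihood 0).
The likelihood is not conditioned on survival by default; see below.

**Numerics.** The state space reaches 3,472 ranges for 14 fully connected
areas, so dense matrix exponentials are wasteful; we compute the action
`exp(Qt)v` by Poisson-truncated uniformization on the sparse rate matrix
(truncation tail 1e-13, compiled loop), with per-node rescaling of partial
likelihoods. Rate matrices are assembled per evaluation from precomputed
per-slice transition skeletons. Maximum-likelihood estimation runs
Nelder–Mead on log(d), log(e) from two starts spanning two orders of
magnitude, with the box [1e-8, 10] per Myr enforced by a penalty wall; the
log parameterization keeps the simplex well scaled, and a derivative-free
method avoids the long line-search excursions into high-rate regions where
uniformization is expensive.

**Survival conditioning.** Classic DEC treats the null range as absorbing and
leaves the likelihood unconditioned, so survivor-only data push the
extirpation MLE toward zero: every surviving branch testifies against *e*.
`dec_loglik(..., condition = "branch_survival")` divides each branch kernel
by the probability that the lineage escaped absorption on that branch, given
its older-end state. This is exactly the distribution produced by the
simulator's `condition_survival = TRUE` (branch-wise rejection against the
null range), so simulation and inference form a consistent pair; the
parameter-recovery tests use it on both sides. The default remains the
unconditioned classic likelihood.

## Ancestral ranges and the "equally likely" set

Marginal ancestral probabilities combine the below-node partials with an
above-node pass that re-roots through the cladogenetic distribution; at each
node, ranges disallowed in the node's slice get probability zero and the
remainder is renormalized ("relative probability"). Ties rank by smaller
range then bitmask order. The set of ranges whose log marginal likelihood is
within 2 units of the best is flagged "equally likely". Marginal (not joint)
estimates are what the tables report; a joint reconstruction is a possible
future addition.

## Event extraction

Events are counted from point estimates, not stochastic mapping. At each
internal node the inheritance scenario is chosen among the parent range's
cladogenetic outcomes as the one minimizing the anagenetic changes implied on
the two daughter branches (ties: fewer dispersals, then deterministic outcome
order); the scenario is classified as vicariance, subset sympatry or
sympatry, and the residual per-area differences on each branch become
dispersal (one event per gained area, with one "out of" count per source
area — deliberately an overcount when the source range is wide) and
extirpation events. Anagenetic events are dated at branch midpoints; if the
midpoint's slice cannot support the event (no connectivity from any source
area), the date snaps to the midpoint of the nearest branch sub-interval
where it can, and events possible nowhere on the branch keep the midpoint
with an `unconstrained` flag. Extirpations are never snapped: area loss does
not depend on connectivity.

Because vicariance corners can absorb range changes that the true history
realized anagenetically, extracted totals are a parsimony-style lower bound
rather than an unbiased count; the tests verify exact agreement with the
replayed truth precisely on realizations whose true history is minimal, and
rank correlation of per-branch counts elsewhere.

## Latitudinal span through time

Tip latitudes (extant means and fossil paleolatitudes, both precomputed
inputs) evolve by Brownian motion with a piecewise-constant directional
trend: branch increments are Normal with mean `sum_k mu_k t_k` (time spent in
each trend bin, default bins = the geological slices) and variance
`sigma2 t`. Internal-node latitudes are sampled explicitly
(data augmentation), which makes the span reconstruction direct. Traits are
rescaled by 10 internally to help mixing; reported posteriors are
back-transformed. Priors on the rescaled scale: half-Cauchy(1) on `sigma2`,
Normal(0, 10) on each `mu_k`, Normal(0, 50) on the root. Proposals are
sliding windows for node states and trends and multiplicative steps for
`sigma2`, auto-tuned during burn-in only (10% of the default 100,000
generations; thinning 100). Zero-length sampled-ancestor branches get a
1e-4 Myr floor so their increment densities stay proper.

With a posterior tree sample, one chain runs per tree and the thinned draws
are pooled with equal weight — the same posterior mixture as switching trees
within one chain, without remapping latent states between topologies. The
span envelope interpolates every lineage's latitude at each grid time and
pools draws; both a quantile envelope (default 2.5–97.5%) and the absolute
min/max are available, since either reading of a published span polygon is
defensible. A directional trend is unidentifiable from extant (age-0) tips
alone — fossil paleolatitudes are what anchor it, which is why the recovery
simulations use fossil-bearing trees.

The cited variable-trend implementation is not fully specified in print;
this module is therefore a documented, testable stand-in with the
parameterization above, not a line-by-line port.

## Synthetic data

`simulate_fbd_tree()` runs a forward birth–death simulation with Poisson
fossil sampling; fossil samples become zero-length terminal branches (sampled
ancestors) so the tree stays strictly binary, and extant tips are retained
with probability rho. `simulate_dec_history()` is a Gillespie simulation from
the same transition skeletons as the likelihood, drawing cladogenetic
outcomes from the in-state-space table; lineages absorbed into the null
range are extinct-in-place (topology unchanged, tips unobservable).
`simulate_latitudes()` draws trended BM values for every node.

`make_paper_like_fixture()` assembles a study-shaped dataset: a tree of
roughly 320 extant plus 60 fossil tips with a root in 296–358.9 Ma
(FBD rates lambda = log(n)/330 + 0.02, mu = 0.02, psi = 0.0026, rho = 0.87,
origin 330 Ma, rejection-sampled into those bands), a DEC history with
d = 0.0004, e = 0.0035 per Myr conditioned on branch survival — chosen once
so that at least 95% of tips occupy a single area, as in the empirical data
— '?'-coded fossil ranges, and latitudes with a poleward-then-equatorward
trend (root +25 degrees; per-slice drifts +0.05, +0.12, 0, −0.25 deg/Myr from
oldest to youngest around a BM rate of 2 deg²/Myr).

What passing on this fixture shows: every stage runs end-to-end on data with
the empirical shape (size, fossil fraction, coding, time span), estimates are
internally consistent, and outputs are byte-reproducible under a seed. What
it does not show: agreement with any empirical dataset — real ranges are not
generated by a stationary DEC process, real connectivity is not 0/1, and
fossil sampling is far from Poisson-homogeneous.

## Problem sizes used by the checks

The test suite verifies the pruning likelihood against a dense brute-force
oracle on all trees up to 4 tips and 3 areas; recovers d and e (medians
within 35%) from 20 survivor-conditioned datasets on deep, fossil-rich FBD
trees of 150–280 tips with 5 areas; recovers a two-bin ±0.3 deg/Myr trend
(95% CI coverage in at least 8 of 10 runs) on 80–160-tip trees; and checks
event extraction against replayed truth. The acceptance script runs the full
14-area workflow on a 200-extant/40-fossil fixture and a 20,000-generation
latitude chain — sizes chosen so a complete run stays comfortable on one CPU
while leaving every moving part exercised.

## Known limitations

- Dispersal rates are equal across area pairs; no dispersal-multiplier
  matrices (by design).
- Event counts derive from point estimates; no stochastic mapping.
- The branch-survival conditioning is per-branch, not a joint conditioning on
  the observed tree, and the FBD simulator is a data generator, not an
  inference engine.
- Marginal ancestral ranges can be mutually inconsistent between adjacent
  nodes; the event walk resolves this parsimoniously rather than jointly.
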