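---
title: "Quantifying spatial fiber-type distributions on muscle sections"
author: "myofibspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial fiber-type distributions on muscle sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Skeletal muscles mix slow (type I) and fast (type II, subtypes IIa/IIb/IIx)
fibers, and the *spatial arrangement* of those types across a cross-section
carries biological signal: denervation–reinnervation cycles in aging and
neuromuscular disease produce contiguous clumps of like-type fibers, while
healthy muscle often shows characteristic smooth gradients (e.g. the
deep-to-superficial type gradient of the rodent tibialis anterior). The
input to every method here is minimal and standard: a CSV with one row per
fiber giving the centroid coordinates `(x, y)` and a categorical type
label. Coordinates are unitless — every statistic in the package is
invariant to translation, rotation, and uniform rescaling, which the test
suite asserts.

`myofibspat` implements a graded toolkit over such data:

1. **Geometry** — a neighbor network from the pruned Delaunay
   triangulation of the centroids, an alpha-shape boundary polygon, and a
   Voronoi tessellation clipped to that boundary (for display and for
   defining adjacency).
2. **Summary tests** — mean like-type cluster size with a permutation
   envelope; the unlike-neighbor-pairs (join-count) test with analytic
   null moments; the descriptive "abnormally grouped" proportion.
3. **A binary Markov random field** (autologistic model) fitted by
   maximum pseudolikelihood, with a permutation envelope for the
   interaction parameter.
4. **Penalized logistic and multinomial GAMs** that map the *probability*
   of each type as a smooth surface over the section.
5. **A synthetic-section simulator** that makes every method testable
   without histological data, plus batch/cohort comparison utilities.

## Geometry: who is whose neighbor?

All neighbor-based statistics depend on an undirected graph over fibers.
We take the Delaunay triangulation of the centroids (`deldir`) and prune
it, because raw Delaunay graphs contain spurious long edges along the
convex hull and across concavities of the section outline:

* **Length rule** — drop edges longer than `Q3 + 1.5 * IQR` of the edge
  length distribution. The rule is relative, hence scale-invariant, and
  1.5 is the conventional box-plot whisker multiplier; both are exposed in
  `prune_config()`.
* **Boundary rule** — drop edges whose midpoint falls outside the section
  boundary polygon, which removes links that bridge bays in a concave
  outline.

The boundary itself is an alpha shape: Delaunay triangles with
circumradius above `alpha` are discarded and the outline of the remaining
union is traced. `alpha` defaults to twice the median Delaunay edge
length, which tracks the local packing density; `alpha = Inf` gives the
convex hull, and any `alpha` small enough to fragment the shape falls
back to the convex hull with a warning. On jittered-lattice packings the
unpruned network has mean degree ≈ 6 (a Delaunay property the tests
assert), and pruning mostly affects the rim.

The tessellation clips each fiber's Voronoi cell to the boundary polygon
(`spatstat.geom::dirichlet`); cell areas are checked to tile the boundary
area within 0.5%. Note one numerical caveat: polygon clipping rounds
vertices at about 1e-7 relative precision, so containment checks for
points that sit *exactly on* a polygon edge (boundary fibers generate
such points by construction) use a `1e-6`-relative tolerance.

## Summary statistics and their nulls

Throughout, fiber types are encoded as spins: slow = −1, fast = +1
(`encode_binary()`; the fast label set is always explicit, labels are
trimmed and compared case-insensitively, and no "I"/"II" guessing is
done). The shared null model is *randomization with fixed counts*:
labels are shuffled over fiber positions, preserving the observed
slow/fast totals.

**Mean cluster size.** A cluster is a connected component of the
subgraph induced by fibers of the target type (default: the less
prevalent type). The statistic is `#target fibers / #clusters`, compared
against the 2.5th–97.5th percentiles of the same statistic over 999
random relabelings (95% permutation envelope; count and seed are
arguments and are recorded in the result). Above the envelope means
like-type attraction, below means repulsion. The result carries a
reliability flag implementing the standard guideline that the test is
trustworthy only when the target type is under 30% of fibers — near
balance the target subgraph percolates and the statistic loses power, a
caveat the package surfaces rather than hides.

**Unlike neighbor pairs.** The count `U` of network edges joining
different types. Under fixed-count randomization the first two moments
are available in closed form; we derive them directly from ordered pairs
of edges (same edge / edges sharing a vertex / disjoint edges, each with
its hypergeometric-type probability), which is algebraically equivalent
to the classical nonfree-sampling join-count moments. Because the
derivation is easy to get subtly wrong, the test suite checks it against
exhaustive enumeration over all labelings on small graphs — the
enumeration oracle, not the formula, is the ground truth. The test
statistic `z = (U − E U)/sqrt(Var U)` is referred to a standard normal,
two-sided; significantly negative means like-type attraction (a deficit
of unlike pairs), positive means segregation.

**Abnormally grouped fibers.** A descriptive proportion, not a test. For
a target-type fiber of degree `d`, the number of like-type neighbors
under randomization is hypergeometric with mean `d (n_t − 1)/(n − 1)`.
Fibers exceeding their own null mean by more than one null standard
deviation are *marked*; any like-type cluster containing at least two
adjacent marked fibers is flagged whole, and the statistic is the flagged
fraction of target fibers. Two choices here were genuinely open and are
exposed as configuration: the null may instead be estimated by pooled
permutation (`null_method = "permutation"`, 999 relabelings), and the
"at least two neighboring fibers" rule is parameterized as
`min_marked`. The default (analytic, per-fiber thresholds, `min_marked
= 2`) is the closest literal reading. The proportion rises mechanically
with the overall target fraction (the tests reproduce this monotone
trend), so it should only be compared between sections of similar
composition.

## The binary Markov random field

The autologistic model places probability proportional to
`exp(alpha * sum_i z_i + beta * sum_{i~j} z_i z_j)` on spin
configurations, where the interaction sum runs over network edges.
`alpha` captures the slow/fast balance; `beta` is the quantity of
interest — positive values mean like-type attraction, negative
repulsion, and unlike the summary tests its magnitude is interpretable at
any type composition. The full likelihood involves an intractable
normalizing constant, so we maximize the **pseudolikelihood**: the
product of per-fiber conditionals
`Pr(Z_i = z | rest) = plogis(2 z (alpha + beta S_i))`, `S_i` the sum of
neighboring spins. This is exactly a logistic regression of
`(z_i + 1)/2` on `S_i` with coefficients `(2 alpha, 2 beta)`, so the fit
is delegated to IRLS (`stats::glm`, deviance tolerance 1e-12) and is
deterministic; the tests verify the optimum against direct numerical
maximization to 1e-6 and check the exact spin-flip symmetry (negating
all spins negates `alpha` and preserves `beta`). Perfect separation — an
exact chequerboard — has no finite maximum; the fit is then bounded at
`|alpha|, |beta| <= 10` and flagged.

Significance of `beta` uses the same fixed-count permutation null:
`beta_permutation_envelope()` refits the model on 999 relabelings
(2.5/97.5 percentiles, linear interpolation; a 2-parameter Newton solver
in C++ keeps the thousand refits cheap, and the suite pins it to the glm
route to 1e-6). Calibration is checked by simulation: under random
labels the estimate falls inside its own envelope ~95% of the time.

The simulator side (`simulate_bmrf_labels()`) draws from the same model
by Gibbs sampling — random-scan sweeps resampling each spin from its
full conditional — with a 500-sweep default burn-in; at the weak
interactions relevant here (|beta| < 0.1) mixing is fast, and the
parameter-recovery simulations (true `(−0.2, 0.06)` on a 40×40 lattice,
200 replicates) bound the estimator bias below (0.05, 0.02).

## Probability surfaces: logistic and multinomial GAMs

The model-based map asks *where* a type is likely, not just whether types
cluster. The log odds of a fiber being fast is modeled as a smooth
surface in its coordinates: an intercept, linear terms in `x` and `y`,
and `K − 3` thin-plate spline basis functions built from the radial
kernel `r^2 log r`. Construction details that matter:

* Coordinates are centered and scaled by their root-mean-square radius
  before any kernel evaluation — `r^2 log r` is badly conditioned across
  scales, and this standardization is what makes the fitted surface
  invariant (to 1e-6, asserted) under rescaling of the input units.
* Knots are a deterministic space-filling subset of the data (greedy
  farthest-point selection), so fits are reproducible without a seed.
* The thin-plate side conditions are absorbed by reparametrizing through
  the null space of the polynomial constraint, which makes the roughness
  penalty positive semi-definite with the affine surface exactly
  unpenalized. `K = 3` degenerates to plain logistic regression on
  `(x, y)`, and `lambda -> Inf` drives any `K` to that same plane (an
  asserted limiting identity; effective degrees of freedom go to 3).
* Basis dimension defaults to `K = min(30, floor(n/4)) + 3` — enough for
  the section-scale trends of interest at ~1000–2500 fibers while
  keeping a fit under a second; `K` is an argument when more resolution
  is wanted.

Coefficients maximize the penalized Bernoulli log-likelihood
`l(beta) − (lambda/2) beta' S beta` by penalized IRLS with step-halving
(gradient-based convergence flag on the result). The smoothing parameter
is selected by a Laplace-approximate REML criterion (default; GCV
available), minimized over a 17-point log-spaced grid on
`lambda ∈ [1e-4, 1e8]` refined by golden-section search — deterministic
given data, with a warning when the optimum sits on the search boundary
(which is the *expected* outcome for pure-noise or purely affine
fields, where maximal smoothing is correct). `mgcv` fits the same model
class; the test suite uses it as an independent cross-check of the
fitted surfaces, while the implementation here is self-contained.

The multinomial extension handles three or more types with `C − 1`
smooth log-odds surfaces against a reference (the most frequent type, a
stability choice invisible in the reported per-type probabilities) and a
softmax link, fitted by full Newton iteration on the penalized
multinomial likelihood. Each surface gets its own `lambda`, selected on
the corresponding type-vs-reference binary subfit and then held fixed in
the joint fit — a pragmatic approximation to joint selection that is
exact in the two-type case, where the multinomial path reduces to the
binary fit to 1e-6 (asserted). Per-fiber probabilities sum to one to
1e-10 on any grid. Surfaces are rendered by `predict_probability_grid()`
on a regular grid (default 100×100) masked to the boundary polygon.

The GAM deliberately takes **no input from the neighbor network** — only
coordinates, labels, and (for masking) the boundary polygon — so the two
model families give genuinely independent views of the same section.

## What the simulator does and does not emulate

`generate_lattice_section()` produces jittered rectangular lattices:
roughly uniform packing, mean degree ≈ 6, section sizes of order
400–2500 fibers — the aspects of real sections that the statistics are
sensitive to. Labels come either from the autologistic model (Gibbs)
with controllable `(alpha, beta)` or from an explicit probability
surface (constant, linear gradient, radial, or any user function). Not
emulated: fiber size/shape variation (cells are near-uniform), real
section outlines (lattices are rectangles; the boundary machinery is
exercised separately on curved clouds), hybrid or mis-typed fibers, and
systematic digitization artifacts. Green tests on synthetic sections
therefore validate the *statistical machinery*, not the upstream typing
pipeline of any particular histology workflow.

The packaged validation uses fixed, documented problem sizes: 45×45
sections (~2000 fibers, the scale of a mouse soleus section) for the
three-regime walkthrough with slow-majority balance `alpha = −0.25` and
interactions `beta = 0, +0.12, −0.25` — forward-chosen so that the three
regimes are unambiguous at that scale; 40×40 lattices with 500/300/150
replicates for null calibration of the two tests and the envelope; 200
replicates for parameter recovery; 50 surface-recovery replicates for
the GAM (mean absolute probability error < 0.05 against the generating
field).

## Numerical and degenerate-input policy

* Conditional probabilities are always evaluated through
  `plogis(..., log.p = TRUE)`; no `exp` overflow at extreme parameters.
* Permutation envelopes use `quantile(type = 7)` (linear interpolation)
  at 2.5/97.5%; all permutation counts and seeds are stored in results
  and serialized by `write_results()`.
* Degenerate inputs fail loudly and specifically: collinear point sets,
  duplicate coordinates (offending rows listed), single-type sections,
  empty fast/slow groups, centroids outside a supplied boundary (fiber
  ids named), zero null variance. A disconnected pruned network only
  warns, since every statistic remains well defined.
* The `n >= 3`, no-duplicate, finite-coordinate invariants are enforced
  at construction; the two-type invariant at CSV validation and
  encoding, so unlabeled simulator output can exist transiently.

## Known limitations

* Pseudolikelihood is consistent but not efficient; near-critical
  interactions (|beta| approaching 1 on a degree-6 graph) are outside
  the intended regime and the simulator warns there.
* The printed per-section numbers in the literature this toolkit
  mirrors depend on the exact neighbor-pruning conventions of their
  geometric pipelines; with a different pruning rule, observed counts
  (and hence test statistics) shift by a few percent. The pruning here
  is fully configurable and documented, and verdict-level conclusions
  are robust to it in our simulations.
* Group comparisons treat per-section parameter estimates as data
  (Welch t test and Mann–Whitney U in `compare_group_params()`);
  hierarchical models that propagate per-section uncertainty are out of
  scope.
* Probability surfaces carry no uncertainty bands; they are point
  estimates for visualization and comparison.
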