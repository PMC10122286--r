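# myofibspat

Spatial statistics for muscle fiber-type distributions on histological
cross-sections.

Muscle fibers come in slow (type I) and fast (type II: IIa/IIb/IIx)
varieties, and their spatial arrangement across a section changes with age
and neuromuscular disease — denervation–reinnervation produces contiguous
like-type clumps that a trained eye can see but rarely quantifies.
`myofibspat` takes the minimal digitized representation of a stained
section — a CSV of fiber centroids `(x, y)` with a type label per fiber —
and provides an integrated toolkit to test, model and map those
arrangements:

- **Neighbor geometry.** Pruned Delaunay neighbor network, alpha-shape
  section boundary, Voronoi tessellation clipped to the boundary
  (`delaunay_network()`, `boundary_polygon()`, `tessellation()`).
- **Summary tests.** Mean like-type cluster size against a 95%
  permutation envelope; the unlike-neighbor-pairs (join count) test with
  exact nonfree-sampling null moments; the descriptive
  "abnormally grouped" fiber proportion (`summary_tests()` and friends).
- **Binary Markov random field.** The autologistic model
  `Pr(Z = z) ∝ exp(α Σᵢ zᵢ + β Σ_{i∼j} zᵢ zⱼ)` over the neighbor network
  (spins: slow = −1, fast = +1), fitted by maximum pseudolikelihood via
  its logistic-regression reduction; `α` measures type balance, `β`
  like-type attraction (+) or repulsion (−), with a permutation envelope
  for `β = 0` (`fit_bmrf()`, `fit_bmrf_with_envelope()`).
- **Probability surfaces.** A penalized logistic GAM,
  `logit p(x, y) = β₀ + β₁x + β₂y + Σₖ βₖ bₖ(x, y)` over a thin-plate
  regression spline basis with REML-selected smoothing, mapping the
  probability of a type at every location; a multinomial extension for
  3+ types whose per-point probabilities sum to one
  (`fit_logistic_gam()`, `fit_multinomial_gam()`,
  `predict_probability_grid()`).
- **Simulation & cohorts.** Jittered-lattice sections, Gibbs-sampled
  autologistic labels, surface-driven labels (`generate_lattice_section()`,
  `simulate_bmrf_labels()`, `simulate_surface_section()`); batch fitting
  over manifests and two-group comparison of per-section `(α̂, β̂)`
  (`batch_fit()`, `compare_group_params()`).

A command-line front end (`exec/myofibspat`) exposes the same pipeline as
subcommands (`simulate`, `geometry`, `tests`, `bmrf`, `gam`, `batch`,
`compare`).

## Worked example

Simulate a soleus-like section (~2000 fibers, slow majority, like-type
attraction `β = 0.12`) and run the full per-section analysis:

```r
library(myofibspat)

pts <- generate_lattice_section(45, 45, jitter = 0.25, seed = 11)
net <- delaunay_network(pts)
lab <- simulate_bmrf_labels(net, alpha = -0.25, beta = 0.12, seed = 12)
sec <- fiber_section(pts$x, pts$y, ifelse(lab$z == 1, "IIA", "I"))

summary_tests(sec, fast_labels = "IIA", n_perm = 999, seed = 13)
#> Binary labels: n=2025, slow=1550 (76.5%), fast=475 (23.5%)
#> Neighbor network: n=2025 fibers, m=5901 edges, mean degree 5.83
#> Mean cluster size test (target spin +1)
#>   mean cluster size: 3.01 over 158 clusters
#>   95% permutation envelope: (2.17, 2.6)  [n_perm=999]
#>   verdict: attraction
#> Unlike neighbor pairs test
#>   observed U = 1872, expected 2120.0 (var 870.6)
#>   z = -8.407, two-sided p = 4.21e-17 -> attraction
#> % abnormally grouped slow fibers: 99.6%
#> % abnormally grouped fast fibers: 52.6%

fit_bmrf_with_envelope(net, encode_binary(sec, "IIA"),
                       n_perm = 999, seed = 14)
#> Binary Markov random field (maximum pseudolikelihood)
#>   alpha = -0.272  (balance: 1550 slow, 475 fast)
#>   beta  = 0.1111  (interaction)
#>   envelope for beta = 0: (-0.03669, 0.03071)  [n_perm=999] -> attraction
```

Reading the output: the mean fast-fiber cluster (3.01 fibers) exceeds the
permutation envelope, the section shows a ~250-pair deficit of unlike
neighbors (z = −8.4), and the fitted interaction `β̂ = 0.111` — close to
the generating 0.12 — lies far above its null envelope: three independent
routes agreeing on like-type attraction. `α̂ = −0.27` reflects the slow
majority. The probability map of the fast phenotype comes from the GAM,
which uses only coordinates (no neighbor network):

```r
gfit <- fit_logistic_gam(sec, "IIA")
#> Logistic GAM (thin-plate spline surface)
#>   n = 2025, K = 33, lambda = 21.69 (REML), edf = 7.96
#>   deviance = 2176.63, converged: TRUE
surf <- predict_probability_grid(gfit, boundary_polygon(sec))
plot(surf, section = sec)              # heatmap with fibers overlaid
surface_as_data_frame(surf, "surface.csv")
```

Real sections enter the same pipeline through
`read_section_csv("section.csv")` (columns `x`, `y`, `type`, or any
dialect via `column_map=`), or from a shell:

```sh
myofibspat tests --in section.csv --fast-labels IIA --n-perm 999 --seed 1 --out results.json
```

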