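# Synthetic sections with known spatial structure. All generators are pure
# functions of (inputs, seed): the caller's RNG state is left untouched.

#' Generate a jittered-lattice section
#'
#' Emulates the centroid packing of a muscle cross-section as a rectangular
#' lattice (unit spacing) with uniform jitter. Types are set to the single
#' placeholder label `"unlabeled"`; use [simulate_bmrf_labels()] or
#' [simulate_surface_section()] to assign fiber types.
#'
#' @param rows,cols lattice dimensions (`rows * cols >= 9`).
#' @param jitter jitter amplitude as a fraction of the spacing, in `[0, 0.5)`.
#' @param seed integer seed; the result is deterministic given it.
#' @return A [fiber_section] with `rows * cols` fibers.
#' @export
generate_lattice_section <- function(rows, cols, jitter = 0.2, seed = NULL) {
  stopifnot(rows * cols >= 9, jitter >= 0, jitter < 0.5)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  with_local_seed(seed, {
    x <- g$col + stats::runif(nrow(g), -jitter, jitter)
    y <- g$row + stats::runif(nrow(g), -jitter, jitter)
    fiber_section(x, y, rep("unlabeled", nrow(g)))
  })
}

#' Simulate fiber types from the binary Markov random field
#'
#' Draws a label configuration from the autologistic model
#' `Pr(Z = z) propto exp(alpha * sum z_i + beta * sum_{i~j} z_i z_j)`
#' by Gibbs sampling on the supplied neighbor network: fibers are swept in
#' random order, each spin resampled from its full conditional
#' `Pr(Z_i = +1 | rest) = plogis(2 alpha + 2 beta S_i)` with `S_i` the sum
#' of neighboring spins. `alpha` sets the slow/fast balance, `beta` the
#' like-type interaction (positive = attraction, negative = repulsion).
#'
#' @param network a `neighbor_network`.
#' @param alpha,beta model parameters.
#' @param n_sweeps full Gibbs sweeps (burn-in); default 500, which mixes
#'   quickly at the weak interactions (|beta| < 0.1) typical of sections.
#' @param seed integer seed.
#' @return A `binary_labels` object (the final Gibbs state).
#' @export
simulate_bmrf_labels <- function(network, alpha, beta, n_sweeps = 500,
                                 seed = NULL) {
  stopifnot(is.finite(alpha), is.finite(beta), n_sweeps >= 1)
  if (n_sweeps < 100)
    message("n_sweeps < 100: treat the state as unconverged burn-in")
  if (abs(beta) > 1)
    warning("|beta| > 1: near-critical/frozen regime, mixing may be slow",
            call. = FALSE)
  csr <- network_csr(network)
  with_local_seed(seed, {
    z0 <- ifelse(stats::runif(network$n) < stats::plogis(2 * alpha), 1L, -1L)
    z <- .cpp_gibbs_autologistic(csr$ptr, csr$idx, z0, alpha, beta,
                                 as.integer(n_sweeps))
    binary_labels_from_z(z)
  })
}

#' Probability-surface specifications
#'
#' Define a smooth type-probability field `p(x, y)` over a section domain,
#' used by [simulate_surface_section()] to generate spatially structured
#' labels. `surface_constant` gives a flat field; `surface_linear` a linear
#' gradient between the domain extremes along `x` or `y`; `surface_radial`
#' interpolates from `p_center` at the centroid cloud's center to `p_edge`
#' at its maximum radius; `surface_custom` wraps any `function(x, y)`.
#'
#' @param p,p_min,p_max,p_center,p_edge probabilities in `(0, 1)`.
#' @param axis `"x"` or `"y"` for the linear gradient.
#' @param f a vectorized `function(x, y)` returning probabilities.
#' @return A `surface_spec` object (a function of `(x, y)` with metadata).
#' @name surface_spec
NULL

new_surface_spec <- function(f, kind, params = list()) {
  structure(f, kind = kind, params = params, class = "surface_spec")
}

#' @rdname surface_spec
#' @export
surface_constant <- function(p) {
  stopifnot(p >= 0, p <= 1)
  new_surface_spec(function(x, y) rep(p, length(x)), "constant", list(p = p))
}

#' @rdname surface_spec
#' @export
surface_linear <- function(p_min = 0.1, p_max = 0.9, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(p_min > 0, p_min < 1, p_max > 0, p_max < 1)
  new_surface_spec(function(x, y) {
    v <- if (axis == "x") x else y
    t <- (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
    p_min + t * (p_max - p_min)
  }, "linear-gradient", list(p_min = p_min, p_max = p_max, axis = axis))
}

#' @rdname surface_spec
#' @export
surface_radial <- function(p_center = 0.2, p_edge = 0.8) {
  stopifnot(p_center > 0, p_center < 1, p_edge > 0, p_edge < 1)
  new_surface_spec(function(x, y) {
    r <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    t <- r / max(r, .Machine$double.eps)
    p_center + t * (p_edge - p_center)
  }, "radial", list(p_center = p_center, p_edge = p_edge))
}

#' @rdname surface_spec
#' @export
surface_custom <- function(f) {
  stopifnot(is.function(f))
  new_surface_spec(function(x, y) {
    p <- f(x, y)
    if (any(p < 0 | p > 1)) stop("surface must map into [0, 1]", call. = FALSE)
    p
  }, "custom")
}

#' Label a section from a smooth probability surface
#'
#' Each fiber is labeled `"fast"` independently with probability
#' `p(x_i, y_i)` given by the surface specification, else `"slow"`.
#'
#' @param points a [fiber_section] (labels, if any, are ignored).
#' @param spec a [surface_spec] (see [surface_constant()] and friends), or a
#'   plain `function(x, y)`.
#' @param seed integer seed.
#' @param labels length-2 character vector `c(fast, slow)` of output labels.
#' @return A labeled [fiber_section]; the drawn probabilities are attached
#'   as attribute `prob_fast`.
#' @export
simulate_surface_section <- function(points, spec, seed = NULL,
                                     labels = c("fast", "slow")) {
  if (!inherits(spec, "surface_spec") && is.function(spec))
    spec <- surface_custom(spec)
  p <- spec(points$x, points$y)
  stopifnot(length(p) == nrow(points), all(p >= 0), all(p <= 1))
  with_local_seed(seed, {
    fast <- stats::runif(nrow(points)) < p
    out <- fiber_section(points$x, points$y,
                         ifelse(fast, labels[1], labels[2]))
    attr(out, "prob_fast") <- p
    out
  })
}

#' Randomly permute labels, preserving type counts
#'
#' A uniformly random relabeling with the observed counts held fixed: the
#' null mechanism behind every permutation envelope in the package.
#'
#' @param labels a `binary_labels` object.
#' @param seed integer seed.
#' @return A `binary_labels` object with permuted spins.
#' @export
permute_labels <- function(labels, seed = NULL) {
  with_local_seed(seed, binary_labels_from_z(sample(labels$z)))
}

# n x n_perm matrix of permuted spin vectors (internal hot path)
permuted_spin_matrix <- function(z, n_perm) {
  vapply(seq_len(n_perm), function(i) sample(z), integer(length(z)))
}
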