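# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately naive (brute force / enumeration) and share no
# code with the package internals they check.

# tiny section fixtures ------------------------------------------------------

square_section <- function() {
  fiber_section(c(0, 1, 1, 0), c(0, 0, 1, 1), c("A", "A", "B", "B"))
}

triangle_section <- function() {
  fiber_section(c(0, 1, 0.5), c(0, 0, 1), c("A", "A", "B"))
}

# a random simple graph as a neighbor_network
random_network <- function(n, p_edge = 0.3, seed = 1) {
  pairs <- t(combn(n, 2))
  set.seed(seed)
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  neighbor_network(n, pairs[keep, , drop = FALSE])
}

# write a section to a temp CSV, returning the path; the file lives until
# the calling frame (normally the test_that block) exits
write_temp_section <- function(sec, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  write_section_csv(sec, path)
  path
}

# oracles --------------------------------------------------------------------

# gift-wrapping (Jarvis march) convex hull area
gift_wrap_area <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    best <- cand[1]
    for (k in cand[-1]) {
      cross <- (x[best] - x[cur]) * (y[k] - y[cur]) -
               (y[best] - y[cur]) * (x[k] - x[cur])
      if (cross < 0 ||
          (cross == 0 && (x[k] - x[cur])^2 + (y[k] - y[cur])^2 >
                         (x[best] - x[cur])^2 + (y[best] - y[cur])^2))
        best <- k
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hx <- x[hull]; hy <- y[hull]
  j <- c(seq_along(hx)[-1], 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# plain union-find component partition over member vertices
union_find_components <- function(n, edges, member) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    if (member[a] && member[b]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(which(member), find, 0L)
  unname(split(which(member), roots))
}

# exhaustive join-count moments: mean/variance of the unlike-pair count over
# all labelings with n1 fibers of type -1 (population moments)
enumerate_join_moments <- function(network, n1) {
  n <- network$n
  e <- network$edges
  subsets <- combn(n, n1)
  U <- apply(subsets, 2, function(idx) {
    z <- rep(1L, n); z[idx] <- -1L
    sum(z[e[, 1]] != z[e[, 2]])
  })
  c(mean = mean(U), var = mean((U - mean(U))^2))
}

# direct per-node conditional log-likelihood summation (no vectorization)
naive_pseudolikelihood <- function(network, z, alpha, beta) {
  total <- 0
  for (i in seq_len(network$n)) {
    S_i <- 0
    for (j in network$adjacency[[i]]) S_i <- S_i + z[j]
    eta <- alpha + beta * S_i
    p_plus <- exp(eta) / (exp(eta) + exp(-eta))
    total <- total + log(if (z[i] == 1) p_plus else 1 - p_plus)
  }
  total
}

# labeled sections emulating the three running soleus examples: slow
# majority, ~n fibers, with random / attraction / repulsion structure
make_example_trio <- function(rows = 45, cols = 45, seed = 101) {
  pts <- generate_lattice_section(rows, cols, jitter = 0.25, seed = seed)
  net <- delaunay_network(pts)
  mk <- function(beta, sd_seed) {
    lab <- simulate_bmrf_labels(net, alpha = -0.25, beta = beta,
                                seed = sd_seed)
    fiber_section(pts$x, pts$y, ifelse(lab$z == 1L, "II", "I"))
  }
  list(random = mk(0, seed + 1),
       attraction = mk(0.12, seed + 2),
       repulsion = mk(-0.25, seed + 3),
       network = net)
}
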