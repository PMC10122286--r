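# Summary- and test-based statistics for binary fiber-type data: mean
# cluster size (permutation test), unlike neighbor pairs (join-count test
# with analytic null moments), and the abnormally-grouped proportion.

check_shapes <- function(network, labels) {
  if (network$n != length(labels$z))
    stop("network (n=", network$n, ") and labels (n=", length(labels$z),
         ") sizes differ", call. = FALSE)
}

#' Like-type connected components
#'
#' "Clusters" in the mean-cluster-size sense: connected components of the
#' subgraph induced by fibers of the target type. Isolated target fibers are
#' singleton clusters.
#'
#' @param network a `neighbor_network`.
#' @param labels a `binary_labels` object.
#' @param target spin of the type of interest: `+1` (fast) or `-1` (slow).
#' @return List of integer vectors of fiber indices, one per component.
#' @export
like_type_components <- function(network, labels, target) {
  check_shapes(network, labels)
  stopifnot(target %in% c(-1L, 1L))
  member <- labels$z == target
  comp <- .cpp_member_components(network$edges, member)
  k <- attr(comp, "n_components")
  if (k == 0L) return(list())
  unname(split(which(member), comp[member]))
}

#' Mean cluster size permutation test
#'
#' Computes the mean size of like-type clusters of the target type (count of
#' target fibers divided by the number of clusters) and compares it against
#' a 95% permutation envelope obtained by randomly relabeling fibers with
#' the type counts held fixed. A mean cluster size above the envelope
#' indicates like-type attraction, below it like-type repulsion. The test is
#' considered reliable when the target type makes up less than 30% of
#' fibers; otherwise `reliability_flag` is set to `FALSE` and the result
#' should be interpreted with caution.
#'
#' @inheritParams like_type_components
#' @param target spin of the type of interest; default the less prevalent
#'   type.
#' @param n_perm number of permutations (>= 199; default 999).
#' @param seed integer seed for the permutations.
#' @return An object of class `cluster_size_result`.
#' @export
mean_cluster_size_test <- function(network, labels, target = NULL,
                                   n_perm = 999, seed = NULL) {
  check_shapes(network, labels)
  if (is.null(target))
    target <- if (labels$n_fast <= labels$n_slow) 1L else -1L
  if (n_perm < 199) stop("n_perm must be at least 199", call. = FALSE)
  n_target <- sum(labels$z == target)
  if (n_target == 0L)
    stop("target type absent from the section", call. = FALSE)
  clusters <- like_type_components(network, labels, target)
  mean_size <- n_target / length(clusters)
  null_means <- with_local_seed(seed, {
    perms <- permuted_spin_matrix(labels$z, n_perm)
    counts <- .cpp_component_counts(network$edges, perms, as.integer(target))
    n_target / counts
  })
  env <- stats::quantile(null_means, c(0.025, 0.975), names = FALSE, type = 7)
  verdict <- if (mean_size > env[2]) "attraction"
             else if (mean_size < env[1]) "repulsion" else "random"
  minority_fraction <- n_target / network$n
  structure(list(target = target, clusters = clusters,
                 mean_size = mean_size,
                 envelope = c(lo = env[1], hi = env[2]),
                 verdict = verdict,
                 minority_fraction = minority_fraction,
                 reliability_flag = minority_fraction <= 0.30,
                 n_perm = n_perm, seed = seed),
            class = "cluster_size_result")
}

#' @export
print.cluster_size_result <- function(x, ...) {
  cat(sprintf("Mean cluster size test (target spin %+d)\n", x$target))
  cat(sprintf("  mean cluster size: %.3g over %d clusters\n",
              x$mean_size, length(x$clusters)))
  cat(sprintf("  95%% permutation envelope: (%.3g, %.3g)  [n_perm=%d]\n",
              x$envelope[1], x$envelope[2], x$n_perm))
  cat("  verdict:", x$verdict, "\n")
  if (!x$reliability_flag)
    cat(sprintf("  caution: target type is %.0f%% of fibers (> 30%% guideline)\n",
                100 * x$minority_fraction))
  invisible(x)
}

#' Count unlike neighbor pairs
#'
#' The join-count statistic `U`: the number of network edges whose two
#' fibers carry different types.
#'
#' @inheritParams like_type_components
#' @return Integer count in `[0, m]`.
#' @export
count_unlike_pairs <- function(network, labels) {
  check_shapes(network, labels)
  z <- labels$z
  sum(z[network$edges[, 1]] != z[network$edges[, 2]])
}

#' Null moments of the unlike-pair count
#'
#' Exact mean and variance of the number of unlike neighbor pairs under
#' uniformly random labelings with fixed type counts (sampling without
#' replacement). Derived from ordered pairs of edges: with `m` edges, `t`
#' pairs of distinct edges sharing a vertex, `n1`/`n2` type counts and
#' `n = n1 + n2`,
#' `E[U] = 2 m n1 n2 / (n (n-1))`, and the second moment sums the
#' probabilities that one, two adjacent, or two disjoint edges are all
#' unlike. Equivalent to the classical nonfree-sampling join-count moments;
#' validated against exhaustive enumeration by the test suite.
#'
#' @param network a `neighbor_network`.
#' @param n_slow,n_fast type counts (must sum to the network's `n`).
#' @return Named numeric vector `c(expected_U, var_U)`; `(0, 0)` when a
#'   count is zero.
#' @export
join_count_moments <- function(network, n_slow, n_fast) {
  n <- n_slow + n_fast
  if (n != network$n)
    stop("counts (", n, ") do not sum to network size (", network$n, ")",
         call. = FALSE)
  if (network$m < 1) stop("network has no edges", call. = FALSE)
  if (n_slow == 0 || n_fast == 0)
    return(c(expected_U = 0, var_U = 0))
  m <- network$m
  n1 <- as.numeric(n_slow); n2 <- as.numeric(n_fast); n <- as.numeric(n)
  # P(one given edge is unlike)
  p1 <- 2 * n1 * n2 / (n * (n - 1))
  # P(two edges sharing a vertex are both unlike)
  p2 <- n1 * n2 * (n1 + n2 - 2) / (n * (n - 1) * (n - 2))
  # P(two vertex-disjoint edges are both unlike)
  p3 <- if (n >= 4)
    4 * n1 * (n1 - 1) * n2 * (n2 - 1) / (n * (n - 1) * (n - 2) * (n - 3))
  else 0
  t_adj <- sum(network$degree * (network$degree - 1) / 2)  # adjacent pairs
  t_dis <- m * (m - 1) / 2 - t_adj                          # disjoint pairs
  EU <- m * p1
  EU2 <- m * p1 + 2 * t_adj * p2 + 2 * t_dis * p3
  c(expected_U = EU, var_U = max(EU2 - EU^2, 0))
}

#' Unlike neighbor pairs test
#'
#' Standardizes the observed unlike-pair count against its analytic null
#' moments: `z = (U - E[U]) / sqrt(Var[U])`, with a two-sided normal
#' p-value. A significantly negative `z` (fewer unlike pairs than expected)
#' indicates like-type attraction; significantly positive indicates
#' like-type segregation/repulsion.
#'
#' @inheritParams like_type_components
#' @param alpha_level significance level for the verdict (default 0.05).
#' @return An object of class `join_count_result`.
#' @export
unlike_pairs_test <- function(network, labels, alpha_level = 0.05) {
  check_shapes(network, labels)
  if (labels$n_slow == 0 || labels$n_fast == 0)
    stop("both types must be present", call. = FALSE)
  U <- count_unlike_pairs(network, labels)
  mom <- join_count_moments(network, labels$n_slow, labels$n_fast)
  if (mom[["var_U"]] <= 0)
    stop("null variance of the unlike-pair count is zero: statistic undefined",
         call. = FALSE)
  z <- (U - mom[["expected_U"]]) / sqrt(mom[["var_U"]])
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p >= alpha_level) "randomness"
             else if (z < 0) "attraction" else "segregation"
  structure(list(observed_U = U,
                 expected_U = unname(mom[["expected_U"]]),
                 var_U = unname(mom[["var_U"]]),
                 z_stat = z, p_value = p, verdict = verdict),
            class = "join_count_result")
}

#' @export
print.join_count_result <- function(x, ...) {
  cat("Unlike neighbor pairs test\n")
  cat(sprintf("  observed U = %d, expected %.1f (var %.1f)\n",
              x$observed_U, x$expected_U, x$var_U))
  cat(sprintf("  z = %.3f, two-sided p = %.4g -> %s\n",
              x$z_stat, x$p_value, x$verdict))
  invisible(x)
}

#' Proportion of abnormally grouped fibers
#'
#' Descriptive statistic for excess like-type grouping of the target type.
#' Under random labeling, the number of like-type neighbors of a target
#' fiber with degree `d` is hypergeometric (drawing `d` of the remaining
#' `n - 1` fibers, `n_t - 1` of which share the type). A target fiber is
#' *marked* when its observed like-type neighbor count exceeds its null mean
#' by more than one null standard deviation. Any like-type cluster that
#' contains at least `min_marked` adjacent marked fibers is classified as
#' abnormally grouped, and *all* of its fibers count towards the reported
#' proportion (flagged / total target fibers).
#'
#' Not a formal test: the proportion grows mechanically with the overall
#' target-type fraction, so compare it only between sections with similar
#' type proportions.
#'
#' @inheritParams like_type_components
#' @param null_method `"analytic"` (per-fiber hypergeometric moments,
#'   default) or `"permutation"` (pooled mean/sd over `n_perm` random
#'   relabelings).
#' @param min_marked minimum number of adjacent marked fibers for a cluster
#'   to be flagged (default 2).
#' @param n_perm,seed permutation settings for
#'   `null_method = "permutation"`.
#' @return An object of class `abnormal_grouping_result`.
#' @export
abnormal_grouping_stat <- function(network, labels, target = -1L,
                                   null_method = c("analytic", "permutation"),
                                   min_marked = 2L, n_perm = 999,
                                   seed = NULL) {
  check_shapes(network, labels)
  null_method <- match.arg(null_method)
  stopifnot(target %in% c(-1L, 1L))
  z <- labels$z
  targets <- which(z == target)
  n_t <- length(targets)
  if (n_t == 0L) stop("target type absent from the section", call. = FALSE)
  if (network$m == 0L) {
    warning("network has no edges: proportion is 0", call. = FALSE)
    return(structure(list(target = target, null_mean = 0, null_sd = 0,
                          flagged_fibers = integer(0), proportion = 0,
                          null_method = null_method),
                     class = "abnormal_grouping_result"))
  }
  # observed like-type neighbor counts of target fibers
  like_count <- vapply(targets, function(i)
    sum(z[network$adjacency[[i]]] == target), 0L)
  n <- network$n
  d <- network$degree[targets]
  if (null_method == "analytic") {
    frac <- (n_t - 1) / (n - 1)
    mu <- d * frac
    vr <- d * frac * (1 - frac) * (n - 1 - d) / (n - 2)
    marked_local <- targets[like_count > mu + sqrt(vr)]
    null_mean <- mean(mu); null_sd <- mean(sqrt(vr))
  } else {
    pooled <- with_local_seed(seed, {
      perms <- permuted_spin_matrix(z, n_perm)
      cnt <- vapply(seq_len(n_perm), function(s) {
        zp <- perms[, s]
        tp <- which(zp == target)
        vapply(tp, function(i) sum(zp[network$adjacency[[i]]] == target), 0L)
      }, integer(n_t))
      c(mean(cnt), stats::sd(as.numeric(cnt)))
    })
    null_mean <- pooled[1]; null_sd <- pooled[2]
    marked_local <- targets[like_count > null_mean + null_sd]
  }
  # flag whole clusters containing >= min_marked adjacent marked fibers
  clusters <- like_type_components(network, labels, target)
  marked <- logical(n); marked[marked_local] <- TRUE
  flagged <- integer(0)
  for (cl in clusters) {
    mk <- cl[marked[cl]]
    if (length(mk) < min_marked) next
    mk_set <- logical(n); mk_set[mk] <- TRUE
    adjacent_pair <- any(vapply(mk, function(i)
      any(mk_set[network$adjacency[[i]]]), logical(1)))
    if (adjacent_pair) flagged <- c(flagged, cl)
  }
  structure(list(target = target, null_mean = null_mean, null_sd = null_sd,
                 marked_fibers = marked_local,
                 flagged_fibers = sort(flagged),
                 proportion = length(flagged) / n_t,
                 n_target = n_t, null_method = null_method,
                 min_marked = min_marked),
            class = "abnormal_grouping_result")
}

#' @export
print.abnormal_grouping_result <- function(x, ...) {
  cat(sprintf("Abnormally grouped fibers (target spin %+d, %s null)\n",
              x$target, x$null_method))
  cat(sprintf("  null like-neighbor count: mean %.3g, sd %.3g\n",
              x$null_mean, x$null_sd))
  cat(sprintf("  flagged %d / %d target fibers = %.1f%%\n",
              length(x$flagged_fibers), x$n_target, 100 * x$proportion))
  invisible(x)
}

#' Run all three summary tests on a section
#'
#' Convenience wrapper reproducing the standard per-section summary table:
#' mean cluster size test on the less prevalent type, unlike neighbor pairs
#' test, and abnormally-grouped proportions for both types.
#'
#' @param section a [fiber_section].
#' @param fast_labels labels to treat as fast (see [encode_binary()]).
#' @param n_perm,seed permutation settings.
#' @param prune network pruning configuration.
#' @return A list of class `section_summary` with components
#'   `cluster_size`, `unlike_pairs`, `abnormal_slow`, `abnormal_fast`,
#'   `network`, `labels`.
#' @export
summary_tests <- function(section, fast_labels, n_perm = 999, seed = NULL,
                          prune = prune_config()) {
  labels <- encode_binary(section, fast_labels)
  network <- delaunay_network(section, prune = prune)
  structure(list(
    cluster_size = mean_cluster_size_test(network, labels, n_perm = n_perm,
                                          seed = seed),
    unlike_pairs = unlike_pairs_test(network, labels),
    abnormal_slow = abnormal_grouping_stat(network, labels, target = -1L),
    abnormal_fast = abnormal_grouping_stat(network, labels, target = 1L),
    network = network, labels = labels),
    class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  print(x$labels)
  print(x$network)
  print(x$cluster_size)
  print(x$unlike_pairs)
  cat(sprintf("%% abnormally grouped slow fibers: %.1f%%\n",
              100 * x$abnormal_slow$proportion))
  cat(sprintf("%% abnormally grouped fast fibers: %.1f%%\n",
              100 * x$abnormal_fast$proportion))
  invisible(x)
}
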