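test_that("like-type components follow the hand-checkable path example", {
  # path a-b-c-d with types (+,+,-,+): components {a,b} and {d}
  net <- neighbor_network(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  lab <- myofibspat:::binary_labels_from_z(c(1L, 1L, -1L, 1L))
  comp <- like_type_components(net, lab, target = 1L)
  sizes <- sort(lengths(comp))
  expect_equal(sizes, c(1L, 2L))
  expect_setequal(unlist(comp), c(1L, 2L, 4L))
  # all-target on a connected graph: one component of size n
  lab_all <- myofibspat:::binary_labels_from_z(c(1L, 1L, 1L, -1L))
  net_k4 <- neighbor_network(4, t(combn(4, 2)))
  expect_equal(lengths(like_type_components(net_k4, lab_all, 1L)), 3L)
})

test_that("unlike-pair count obeys conservation and chequerboard identities", {
  net <- random_network(40, 0.15, seed = 31)
  set.seed(32)
  z <- sample(rep(c(-1L, 1L), 20))
  lab <- myofibspat:::binary_labels_from_z(z)
  U <- count_unlike_pairs(net, lab)
  like <- sum(z[net$edges[, 1]] == z[net$edges[, 2]])
  expect_equal(U + like, net$m)
  # all same type -> 0 handled through raw spins
  expect_equal(count_unlike_pairs(
    net, structure(list(z = rep(1L, 40), n_slow = 0L, n_fast = 40L),
                   class = "binary_labels")), 0L)
  # alternating types on an even cycle: U = m
  cyc <- neighbor_network(6, cbind(1:6, c(2:6, 1)))
  alt <- myofibspat:::binary_labels_from_z(rep(c(1L, -1L), 3))
  expect_equal(count_unlike_pairs(cyc, alt), cyc$m)
})

test_that("join-count moments equal exhaustive enumeration", {
  # triangle with counts (1,2): U = 2 for every labeling, variance 0
  tri <- neighbor_network(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  mom <- join_count_moments(tri, 1, 2)
  expect_equal(unname(mom["expected_U"]), 2)
  expect_equal(unname(mom["var_U"]), 0)
  # structured and random graphs, n = 4..8, every non-degenerate count split
  graphs <- list(
    path5 = neighbor_network(5, cbind(1:4, 2:5)),
    cycle6 = neighbor_network(6, cbind(1:6, c(2:6, 1))),
    star6 = neighbor_network(6, cbind(1L, 2:6)),
    k4 = neighbor_network(4, t(combn(4, 2))),
    k7 = neighbor_network(7, t(combn(7, 2)))
  )
  for (s in 1:8) graphs[[paste0("rnd", s)]] <-
    random_network(sample(4:8, 1), runif(1, 0.25, 0.7), seed = 330 + s)
  for (g in graphs) {
    for (n1 in 1:(g$n - 1)) {
      mom <- join_count_moments(g, n1, g$n - n1)
      want <- enumerate_join_moments(g, n1)
      expect_equal(unname(mom["expected_U"]), unname(want["mean"]),
                   tolerance = 1e-12)
      expect_equal(unname(mom["var_U"]), unname(want["var"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("unlike-pairs test direction maps to attraction vs segregation", {
  pts <- generate_lattice_section(25, 25, 0.25, seed = 33)
  net <- delaunay_network(pts)
  # clustered labels (Gibbs attraction) -> deficit of unlike pairs
  lab_att <- simulate_bmrf_labels(net, -0.1, 0.25, seed = 34)
  res_att <- unlike_pairs_test(net, lab_att)
  expect_lt(res_att$z_stat, 0)
  expect_identical(res_att$verdict, "attraction")
  # chequerboard-ish labels (Gibbs repulsion) -> excess
  lab_rep <- simulate_bmrf_labels(net, 0, -0.4, seed = 35)
  res_rep <- unlike_pairs_test(net, lab_rep)
  expect_gt(res_rep$z_stat, 0)
  expect_identical(res_rep$verdict, "segregation")
  expect_true(res_att$observed_U >= 0 && res_att$observed_U <= net$m)
})

test_that("mean cluster size test flags attraction/repulsion correctly", {
  pts <- generate_lattice_section(25, 25, 0.25, seed = 36)
  net <- delaunay_network(pts)
  # minority type concentrated in one patch: large like-type clusters
  blob <- surface_custom(function(x, y)
    ifelse((x - 8)^2 + (y - 8)^2 < 30, 0.85, 0.03))
  sec_att <- simulate_surface_section(pts, blob, seed = 37)
  lab_att <- encode_binary(sec_att, "fast")
  res <- mean_cluster_size_test(net, lab_att, n_perm = 499, seed = 38)
  expect_identical(res$verdict, "attraction")
  expect_equal(res$mean_size,
               sum(lab_att$z == res$target) / length(res$clusters))
  expect_gt(res$mean_size, res$envelope["hi"])
  # permutation envelope is reproducible given the seed
  res2 <- mean_cluster_size_test(net, lab_att, n_perm = 499, seed = 38)
  expect_identical(res$envelope, res2$envelope)
  # reliability guideline: >30% minority flips the flag
  expect_identical(res$reliability_flag, res$minority_fraction <= 0.30)

  lab_rep <- simulate_bmrf_labels(net, -0.5, -0.4, seed = 39)
  res_rep <- mean_cluster_size_test(net, lab_rep, n_perm = 499, seed = 40)
  expect_identical(res_rep$verdict, "repulsion")
})

test_that("abnormal grouping follows the marked-cluster rule", {
  # two clear slow clusters on a path; hand-construct expectations
  # graph: 1-2-3-4-5-6-7-8 path; slow at 1,2,3 and 6 (singleton-ish)
  net <- neighbor_network(8, cbind(1:7, 2:8))
  z <- c(-1L, -1L, -1L, 1L, 1L, -1L, 1L, 1L)
  lab <- myofibspat:::binary_labels_from_z(z)
  res <- abnormal_grouping_stat(net, lab, target = -1L)
  # fiber 2 has 2 slow neighbors; null mean for degree-2 fiber is
  # 2*(4-1)/(8-1) = 0.857, sd < 1 -> marked; but a flagged cluster needs
  # two adjacent marked fibers
  expect_true(all(res$flagged_fibers %in% which(z == -1L)))
  expect_gte(res$proportion, 0)
  expect_lte(res$proportion, 1)

  # fully clustered slow block on a lattice: the whole block flags
  pts <- generate_lattice_section(12, 12, 0.2, seed = 41)
  net2 <- delaunay_network(pts)
  zz <- ifelse(pts$x <= stats::median(pts$x), -1L, 1L)
  lab2 <- myofibspat:::binary_labels_from_z(zz)
  res2 <- abnormal_grouping_stat(net2, lab2, target = -1L)
  expect_gt(res2$proportion, 0.8)
  # permutation null agrees qualitatively with the analytic null
  res2p <- abnormal_grouping_stat(net2, lab2, target = -1L,
                                  null_method = "permutation",
                                  n_perm = 199, seed = 42)
  expect_gt(res2p$proportion, 0.8)
  expect_equal(res2p$null_mean, res2$null_mean, tolerance = 0.1)
})

test_that("abnormal grouping proportion rises with the target-type fraction", {
  pts <- generate_lattice_section(20, 20, 0.25, seed = 43)
  net <- delaunay_network(pts)
  props <- vapply(c(0.2, 0.4, 0.6), function(f) {
    mean(vapply(1:20, function(r) {
      z <- rep(1L, 400)
      set.seed(1000 * f + r)
      z[sample(400, round(400 * f))] <- -1L
      abnormal_grouping_stat(net, myofibspat:::binary_labels_from_z(z),
                             target = -1L)$proportion
    }, 0))
  }, 0)
  expect_true(all(diff(props) > 0))
})

test_that("envelope machinery is label-swap symmetric in its null", {
  net <- random_network(60, 0.1, seed = 44)
  set.seed(45)
  z <- sample(rep(c(-1L, 1L), c(40, 20)))
  lab <- myofibspat:::binary_labels_from_z(z)
  lab_sw <- myofibspat:::binary_labels_from_z(-z)
  # join-count moments depend only on the count pair (symmetric)
  expect_equal(join_count_moments(net, 40, 20),
               join_count_moments(net, 20, 40))
  # swapped labels with swapped target give the identical statistic
  r1 <- mean_cluster_size_test(net, lab, target = 1L, n_perm = 199, seed = 9)
  r2 <- mean_cluster_size_test(net, lab_sw, target = -1L, n_perm = 199,
                               seed = 9)
  expect_equal(r1$mean_size, r2$mean_size)
  expect_equal(r1$envelope, r2$envelope)
})
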