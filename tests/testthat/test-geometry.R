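test_that("tiny configurations give the exhaustively known edge sets", {
  # unit square: 4 sides + 1 diagonal
  net <- delaunay_network(square_section(),
                          prune = prune_config("none", boundary_clip = FALSE))
  expect_equal(net$m, 5L)
  expect_equal(net$n, 4L)
  # triangle: always 3 edges, whatever the pruning threshold
  net3 <- delaunay_network(triangle_section(), prune = prune_config())
  expect_equal(net3$m, 3L)
  # collinear points are rejected
  bad <- fiber_section(c(0, 1, 2, 3), c(0, 1, 2, 3), c("A", "B", "A", "B"))
  expect_error(delaunay_network(bad), "collinear")
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  pts <- generate_lattice_section(14, 15, jitter = 0.35, seed = 21)  # n=210
  geo <- tessellation(pts)
  tri <- geo$triangulation
  x <- pts$x; y <- pts$y
  circum <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  violations <- 0L
  for (r in seq_len(nrow(tri))) {
    cc <- circum(tri[r, 1], tri[r, 2], tri[r, 3])
    d <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
    inside <- d < cc[3] * (1 - 1e-9)
    inside[tri[r, ]] <- FALSE
    violations <- violations + sum(inside)
  }
  expect_equal(violations, 0L)
  # every unpruned network edge is a triangle edge of this triangulation
  net <- delaunay_network(pts, prune = prune_config("none",
                                                    boundary_clip = FALSE))
  tri_edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  tri_keys <- unique(paste(pmin(tri_edges[, 1], tri_edges[, 2]),
                           pmax(tri_edges[, 1], tri_edges[, 2])))
  net_keys <- paste(net$edges[, 1], net$edges[, 2])
  expect_true(all(net_keys %in% tri_keys))
  # and matches an independent triangulation implementation
  tm <- interp::tri.mesh(pts$x, pts$y)
  arcs <- interp::arcs(tm)
  interp_keys <- paste(pmin(arcs[, 1], arcs[, 2]), pmax(arcs[, 1], arcs[, 2]))
  expect_setequal(net_keys, interp_keys)
})

test_that("mean degree of an unpruned jittered-lattice triangulation is ~6", {
  pts <- generate_lattice_section(15, 15, jitter = 0.3, seed = 22)
  net <- delaunay_network(pts, prune = prune_config("none",
                                                    boundary_clip = FALSE))
  expect_gt(mean(net$degree), 5)
  expect_lt(mean(net$degree), 7)
})

test_that("network edges are invariant to similarity transforms", {
  pts <- generate_lattice_section(12, 12, jitter = 0.3, seed = 23)
  net1 <- delaunay_network(pts)
  th <- 0.7; sc <- 37.5
  xr <- sc * (cos(th) * pts$x - sin(th) * pts$y) + 1000
  yr <- sc * (sin(th) * pts$x + cos(th) * pts$y) - 55
  net2 <- delaunay_network(fiber_section(xr, yr, pts$type))
  expect_identical(net1$edges, net2$edges)
})

test_that("boundary polygon matches the convex hull when alpha = Inf", {
  sec <- square_section()
  poly <- boundary_polygon(sec, alpha = Inf)
  expect_equal(sort(apply(poly, 1, paste, collapse = ",")),
               sort(c("0,0", "1,0", "1,1", "0,1")))
  expect_equal(abs(myofibspat:::polygon_area_signed(poly[, 1], poly[, 2])), 1)

  # convex cloud: area equals the gift-wrapping hull oracle's area
  set.seed(24)
  th <- runif(150, 0, 2 * pi); r <- sqrt(runif(150))
  sec2 <- fiber_section(r * cos(th), r * sin(th),
                        rep(c("A", "B"), 75))
  poly2 <- boundary_polygon(sec2, alpha = Inf)
  a2 <- abs(myofibspat:::polygon_area_signed(poly2[, 1], poly2[, 2]))
  expect_equal(a2, gift_wrap_area(sec2$x, sec2$y), tolerance = 1e-12)
})

test_that("alpha shape tightens into concavities and is ccw and simple", {
  # crescent: ring segment
  set.seed(25)
  th <- runif(400, 0.3 * pi, 1.7 * pi)
  r <- runif(400, 0.7, 1)
  sec <- fiber_section(r * cos(th), r * sin(th), rep(c("A", "B"), 200))
  hull_area <- gift_wrap_area(sec$x, sec$y)
  poly <- boundary_polygon(sec)
  expect_identical(attr(poly, "method"), "alpha_shape")
  a <- myofibspat:::polygon_area_signed(poly[, 1], poly[, 2])
  expect_gt(a, 0)           # counter-clockwise
  expect_lt(a, hull_area)   # concavity carved out
  expect_true(all(myofibspat:::points_in_polygon(sec$x, sec$y, poly)))
  # vertices unique => simple cycle
  expect_false(anyDuplicated(paste(poly[, 1], poly[, 2])) > 0)
  # absurdly small alpha falls back to the hull with a warning
  expect_warning(ph <- boundary_polygon(sec, alpha = 1e-6), "convex hull")
  expect_identical(attr(ph, "method"), "convex_hull")
})

test_that("tessellation cells tile the boundary and contain their centroids", {
  # 2x2 grid in a square: four congruent quarter cells
  sec <- square_section()
  geo <- tessellation(sec, boundary_polygon(sec, alpha = Inf))
  expect_equal(geo$cell_areas, rep(0.25, 4), tolerance = 1e-6)

  pts <- generate_lattice_section(15, 14, jitter = 0.3, seed = 26)
  geo <- tessellation(pts)
  expect_equal(sum(geo$cell_areas) / geo$boundary_area, 1, tolerance = 0.005)
  for (i in seq_len(nrow(pts)))
    expect_true(myofibspat:::points_in_polygon(pts$x[i], pts$y[i],
                                               geo$cells[[i]]))
  # centroid outside the boundary is an error naming the fiber
  shifted <- boundary_polygon(pts, alpha = Inf)
  shifted[, 1] <- shifted[, 1] * 0.5 + mean(pts$x) * 0.5
  shifted[, 2] <- shifted[, 2] * 0.5 + mean(pts$y) * 0.5
  expect_error(tessellation(pts, shifted), "fiber_id")
})

test_that("single interior point ringed by neighbors gets a bounded convex cell", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  sec <- fiber_section(c(0, cos(th)), c(0, sin(th)),
                       rep(c("A", "B"), length.out = 9))
  geo <- tessellation(sec, boundary_polygon(sec, alpha = Inf))
  cell <- geo$cells[[1]]
  # half-plane oracle: the cell of the center point is the intersection of
  # bisector half-planes; all its vertices must be closer to the center
  # than to any ring point (within tolerance)
  for (v in seq_len(nrow(cell))) {
    d0 <- sqrt(cell[v, 1]^2 + cell[v, 2]^2)
    dmin <- min(sqrt((cos(th) - cell[v, 1])^2 + (sin(th) - cell[v, 2])^2))
    expect_lte(d0, dmin + 1e-5)
  }
  # convexity: all cross products of consecutive edges share a sign
  j <- c(seq_len(nrow(cell))[-1], 1)
  k <- c(j[-1], j[1])
  cr <- (cell[j, 1] - cell[, 1]) * (cell[k, 2] - cell[j, 2]) -
        (cell[j, 2] - cell[, 2]) * (cell[k, 1] - cell[j, 1])
  expect_true(all(cr >= -1e-9) || all(cr <= 1e-9))
})

test_that("like-type component partition equals the union-find oracle", {
  net <- random_network(50, 0.08, seed = 27)
  set.seed(28)
  z <- sample(c(-1L, 1L), 50, replace = TRUE)
  lab <- myofibspat:::binary_labels_from_z(z)
  got <- like_type_components(net, lab, target = 1L)
  want <- union_find_components(50, net$edges, z == 1L)
  norm <- function(l) sort(vapply(l, function(v) paste(sort(v), collapse = ","),
                                  ""))
  expect_identical(norm(got), norm(want))
})
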