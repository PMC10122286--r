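# Section geometry: Delaunay neighbor network, alpha-shape boundary,
# clipped Voronoi tessellation. Triangulation via deldir; polygonal window
# operations via spatstat.geom.

#' Pruning configuration for the neighbor network
#'
#' Controls which Delaunay edges are dropped when building the neighbor
#' network. The default removes edges longer than `Q3 + iqr_factor * IQR` of
#' the Delaunay edge-length distribution (a scale-invariant outlier rule)
#' and edges whose midpoint falls outside the section boundary polygon
#' (spurious links bridging concavities).
#'
#' @param length_rule `"iqr"` or `"none"`.
#' @param iqr_factor multiplier on the interquartile range (default 1.5).
#' @param boundary_clip logical; drop edges whose midpoint lies outside the
#'   boundary polygon.
#' @param alpha concavity parameter forwarded to [boundary_polygon()] when
#'   `boundary_clip` is `TRUE` and no boundary is supplied (`NULL` = default).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(length_rule = c("iqr", "none"), iqr_factor = 1.5,
                         boundary_clip = TRUE, alpha = NULL) {
  structure(list(length_rule = match.arg(length_rule),
                 iqr_factor = iqr_factor,
                 boundary_clip = boundary_clip,
                 alpha = alpha),
            class = "prune_config")
}

# Raw Delaunay edges (i < j) and the deldir object; shared by the network
# and boundary constructors.
delaunay_raw <- function(section) {
  n <- nrow(section)
  if (n < 3L) stop("need at least 3 fibers for a triangulation", call. = FALSE)
  i2 <- which(section$x != section$x[1] | section$y != section$y[1])[1]
  ux <- section$x[i2] - section$x[1]; uy <- section$y[i2] - section$y[1]
  cr <- ux * (section$y - section$y[1]) - uy * (section$x - section$x[1])
  if (all(abs(cr) <= 1e-12 * max(ux^2 + uy^2)))
    stop("degenerate geometry: points are collinear", call. = FALSE)
  dd <- deldir::deldir(section$x, section$y, suppressMsge = TRUE)
  e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  len <- sqrt((section$x[e[, 1]] - section$x[e[, 2]])^2 +
              (section$y[e[, 1]] - section$y[e[, 2]])^2)
  list(dd = dd, edges = e, lengths = len)
}

#' Build the pruned Delaunay neighbor network
#'
#' Computes the Delaunay triangulation of the fiber centroids and prunes
#' spurious edges (see [prune_config()]) to obtain the undirected neighbor
#' network over which all neighbor-based statistics are defined. The pruning
#' thresholds are relative to the edge-length distribution, so the edge set
#' is invariant to translation, rotation and uniform scaling.
#'
#' @param section a [fiber_section].
#' @param prune a [prune_config()]; use
#'   `prune_config("none", boundary_clip = FALSE)` to keep every Delaunay
#'   edge.
#' @param boundary optional precomputed boundary polygon (two-column matrix)
#'   used for midpoint clipping; computed internally by default.
#' @return An object of class `neighbor_network`: list with `n`, `edges`
#'   (m x 2 integer matrix, i < j), `m`, `lengths`, `degree`, `adjacency`
#'   (per-fiber integer vectors), and the generating coordinates.
#' @export
delaunay_network <- function(section, prune = prune_config(),
                             boundary = NULL) {
  raw <- delaunay_raw(section)
  e <- raw$edges; len <- raw$lengths
  keep <- rep(TRUE, nrow(e))
  if (prune$length_rule == "iqr" && nrow(e) > 4L) {
    q <- stats::quantile(len, c(0.25, 0.75), names = FALSE)
    thr <- q[2] + prune$iqr_factor * (q[2] - q[1])
    keep <- keep & (len <= thr)
  }
  if (isTRUE(prune$boundary_clip)) {
    if (is.null(boundary))
      boundary <- boundary_polygon(section, alpha = prune$alpha, raw = raw)
    W <- boundary_owin(boundary)
    mx <- (section$x[e[, 1]] + section$x[e[, 2]]) / 2
    my <- (section$y[e[, 1]] + section$y[e[, 2]]) / 2
    keep <- keep & points_in_polygon(mx, my, boundary)
  }
  e <- e[keep, , drop = FALSE]; len <- len[keep]
  n <- nrow(section)
  net <- new_network(n, e, len, section)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (igraph::components(g)$no > 1L)
    warning("neighbor network is disconnected after pruning (",
            igraph::components(g)$no, " components)", call. = FALSE)
  net
}

#' Construct a neighbor network from an explicit edge list
#'
#' Builds the `neighbor_network` container from an arbitrary undirected
#' edge list (e.g. neighbors defined by a method other than the pruned
#' Delaunay triangulation).
#'
#' @param n number of fibers.
#' @param edges two-column matrix of 1-based vertex pairs.
#' @param lengths optional edge lengths (default `NA`).
#' @return A `neighbor_network`.
#' @export
neighbor_network <- function(n, edges, lengths = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (nrow(edges)) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  new_network(n, edges, lengths %||% rep(NA_real_, nrow(edges)))
}

new_network <- function(n, edges, lengths, section = NULL) {
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edge", call. = FALSE)
    if (anyDuplicated(paste(edges[, 1], edges[, 2])))
      stop("duplicate edge", call. = FALSE)
    if (max(edges) > n) stop("edge endpoint out of range", call. = FALSE)
  }
  deg <- tabulate(edges, nbins = n)
  adj <- vector("list", n)
  if (nrow(edges)) {
    both <- c(edges[, 1], edges[, 2])
    nb <- c(edges[, 2], edges[, 1])
    o <- order(both)
    adj <- unname(split(nb[o], factor(both[o], levels = seq_len(n))))
  } else adj <- rep(list(integer(0)), n)
  structure(list(n = n, edges = edges, m = nrow(edges), lengths = lengths,
                 degree = deg, adjacency = adj,
                 x = section$x %||% NULL, y = section$y %||% NULL),
            class = "neighbor_network")
}

#' @export
print.neighbor_network <- function(x, ...) {
  cat(sprintf("Neighbor network: n=%d fibers, m=%d edges, mean degree %.2f\n",
              x$n, x$m, mean(x$degree)))
  invisible(x)
}

#' Export the neighbor network as an edge list
#'
#' @param network a `neighbor_network`.
#' @param path optional CSV path; when given the table `(i, j, length)` is
#'   written there.
#' @return The edge-list data frame, invisibly when written to file.
#' @export
network_edge_list <- function(network, path = NULL) {
  df <- data.frame(i = network$edges[, 1], j = network$edges[, 2],
                   length = network$lengths)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# CSR adjacency (1-based), for the C++ Gibbs sampler
network_csr <- function(network) {
  n <- network$n
  deg <- network$degree
  ptr <- cumsum(c(1L, deg))
  idx <- unlist(network$adjacency, use.names = FALSE)
  list(ptr = as.integer(ptr), idx = as.integer(idx))
}

polygon_area_signed <- function(px, py) {
  j <- c(seq_along(px)[-1], 1L)
  sum(px * py[j] - px[j] * py) / 2
}

boundary_owin <- function(boundary) {
  px <- boundary[, 1]; py <- boundary[, 2]
  if (polygon_area_signed(px, py) < 0) { px <- rev(px); py <- rev(py) }
  spatstat.geom::owin(poly = list(x = px, y = py))
}

# distance from points to the polygon outline (segment distances)
dist_to_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  out <- rep(Inf, length(x))
  for (s in seq_along(px)) {
    vx <- qx[s] - px[s]; vy <- qy[s] - py[s]
    L2 <- vx^2 + vy^2
    t_ <- if (L2 > 0) pmin(pmax(((x - px[s]) * vx + (y - py[s]) * vy) / L2,
                                0), 1) else 0
    d2 <- (x - (px[s] + t_ * vx))^2 + (y - (py[s] + t_ * vy))^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

# containment with a tolerance for points sitting exactly on the outline
# (polygon vertices are fiber centroids, so this is the common case)
points_in_polygon <- function(x, y, boundary) {
  W <- boundary_owin(boundary)
  ok <- suppressWarnings(spatstat.geom::inside.owin(x, y, W))
  if (all(ok)) return(ok)
  # polygon-clipping libraries round vertices near 1e-7 relative
  tol <- 1e-6 * max(diff(range(boundary[, 1])), diff(range(boundary[, 2])))
  idx <- which(!ok)
  ok[idx] <- dist_to_polygon(x[idx], y[idx], boundary) <= tol
  ok
}

#' Boundary polygon of a section
#'
#' Derives a simple polygon approximating the overall shape of the muscle
#' from the fiber centroids, as an alpha shape: Delaunay triangles with
#' circumradius larger than `alpha` are discarded and the boundary of the
#' remaining union is traced. With `alpha = Inf` this is exactly the convex
#' hull. If the chosen `alpha` fragments the shape (multiple boundary
#' cycles, or centroids left outside) the convex hull is returned with a
#' warning.
#'
#' @param section a [fiber_section].
#' @param alpha concavity radius in coordinate units; `NULL` (default) uses
#'   2x the median Delaunay edge length, which tracks the local point
#'   density; `Inf` gives the convex hull.
#' @param raw internal: precomputed [delaunay_raw()] result.
#' @return A two-column matrix of polygon vertices in counter-clockwise
#'   order (class `boundary_polygon`), with attributes `alpha` and `method`
#'   (`"alpha_shape"` or `"convex_hull"`).
#' @export
boundary_polygon <- function(section, alpha = NULL, raw = NULL) {
  if (is.null(raw)) raw <- delaunay_raw(section)
  if (is.null(alpha)) alpha <- 2 * stats::median(raw$lengths)
  hull <- function(reason) {
    if (!is.null(reason)) warning(reason, call. = FALSE)
    ch <- rev(chull(section$x, section$y))  # chull is clockwise
    structure(cbind(x = section$x[ch], y = section$y[ch]),
              class = "boundary_polygon", alpha = alpha,
              method = "convex_hull")
  }
  if (!is.finite(alpha)) return(hull(NULL))
  tl <- deldir::triang.list(raw$dd)
  if (!length(tl)) return(hull("no triangles; using convex hull"))
  circumradius <- function(tr) {
    a <- sqrt((tr$x[1] - tr$x[2])^2 + (tr$y[1] - tr$y[2])^2)
    b <- sqrt((tr$x[2] - tr$x[3])^2 + (tr$y[2] - tr$y[3])^2)
    cc <- sqrt((tr$x[3] - tr$x[1])^2 + (tr$y[3] - tr$y[1])^2)
    ar <- abs(polygon_area_signed(tr$x, tr$y))
    if (ar <= 0) return(Inf)
    a * b * cc / (4 * ar)
  }
  keep <- vapply(tl, circumradius, 0) <= alpha
  if (!any(keep))
    return(hull("alpha too small: no triangles survive; using convex hull"))
  # boundary edges appear in exactly one kept triangle
  ed <- do.call(rbind, lapply(tl[keep], function(tr) {
    p <- tr$ptNum
    cbind(pmin(p, p[c(2, 3, 1)]), pmax(p, p[c(2, 3, 1)]))
  }))
  key <- paste(ed[, 1], ed[, 2])
  bnd <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
  bnd <- unique(bnd)
  # stitch into a single cycle
  vdeg <- table(c(bnd[, 1], bnd[, 2]))
  if (any(vdeg != 2))
    return(hull("alpha too small: boundary is not a simple cycle; using convex hull"))
  nb <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  start <- bnd[1, 1]
  cyc <- integer(nrow(bnd)); cyc[1] <- start
  prev <- -1L; cur <- start
  for (k in seq_len(nrow(bnd))[-1]) {
    nxt <- setdiff(nb[[as.character(cur)]], prev)[1]
    if (is.na(nxt)) return(hull("boundary tracing failed; using convex hull"))
    cyc[k] <- nxt; prev <- cur; cur <- nxt
  }
  if (!cur %in% nb[[as.character(start)]] || length(unique(cyc)) != nrow(bnd))
    return(hull("alpha too small: shape fragments; using convex hull"))
  px <- section$x[cyc]; py <- section$y[cyc]
  if (polygon_area_signed(px, py) < 0) { px <- rev(px); py <- rev(py) }
  poly <- structure(cbind(x = px, y = py), class = "boundary_polygon",
                    alpha = alpha, method = "alpha_shape")
  ok <- points_in_polygon(section$x, section$y, poly)
  if (!all(ok))
    return(hull("alpha too small: centroids fall outside the shape; using convex hull"))
  poly
}

#' Export a boundary polygon as WKT
#'
#' @param boundary a `boundary_polygon`.
#' @return A `POLYGON ((...))` well-known-text string (ring closed).
#' @export
boundary_wkt <- function(boundary) {
  px <- c(boundary[, 1], boundary[1, 1])
  py <- c(boundary[, 2], boundary[1, 2])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.10g %.10g", px, py), collapse = ", "))
}

#' Voronoi tessellation clipped to the section boundary
#'
#' Partitions the boundary polygon into one convex-ish cell per fiber (the
#' Voronoi/Dirichlet cell of its centroid clipped to the boundary), the
#' structure drawn in type-colored section maps. Cell areas sum to the
#' boundary area.
#'
#' @param section a [fiber_section].
#' @param boundary a `boundary_polygon` containing all centroids (default:
#'   computed by [boundary_polygon()]).
#' @return An object of class `section_geometry`: list with `boundary`,
#'   `cells` (per-fiber vertex matrices), `cell_areas`, `boundary_area`, and
#'   `triangulation` (t x 3 matrix of fiber indices).
#' @export
tessellation <- function(section, boundary = NULL) {
  raw <- delaunay_raw(section)
  if (is.null(boundary)) boundary <- boundary_polygon(section, raw = raw)
  W <- boundary_owin(boundary)
  ok <- points_in_polygon(section$x, section$y, boundary)
  if (!all(ok))
    stop("centroid(s) outside boundary polygon: fiber_id ",
         paste(utils::head(section$fiber_id[!ok], 10), collapse = ", "),
         call. = FALSE)
  X <- spatstat.geom::ppp(section$x, section$y, window = W, check = FALSE)
  dt <- spatstat.geom::dirichlet(X)
  tls <- spatstat.geom::tiles(dt)
  areas <- as.numeric(spatstat.geom::tile.areas(dt))
  nm <- suppressWarnings(as.integer(names(tls)))
  if (length(nm) == nrow(section) && !anyNA(nm)) {
    o <- order(nm); tls <- tls[o]; areas <- areas[o]
  }
  cells <- lapply(tls, function(tile) {
    v <- spatstat.geom::vertices(tile)
    cbind(x = v$x, y = v$y)
  })
  tri <- t(vapply(deldir::triang.list(raw$dd),
                  function(tr) as.integer(tr$ptNum), integer(3)))
  structure(list(boundary = boundary, cells = cells, cell_areas = areas,
                 boundary_area = spatstat.geom::area.owin(W),
                 triangulation = tri),
            class = "section_geometry")
}

#' @export
print.section_geometry <- function(x, ...) {
  cat(sprintf(
    "Section geometry: %d cells, boundary area %.4g (cells cover %.2f%%), %d triangles\n",
    length(x$cells), x$boundary_area,
    100 * sum(x$cell_areas) / x$boundary_area, nrow(x$triangulation)))
  invisible(x)
}
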