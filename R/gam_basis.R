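# Low-rank thin-plate regression spline basis over fiber coordinates.
# The smooth log-odds surface is f(x, y) = b0 + b1 x + b2 y +
# sum_k delta_k eta(|s - knot_k|), eta(r) = r^2 log r, with the side
# conditions sum delta = sum delta * knot = 0 absorbed into the
# parametrization so the roughness penalty is positive semi-definite and
# vanishes exactly on affine surfaces (the null space).

tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# deterministic space-filling knot subset: greedy farthest-point selection
# started from the point nearest the centroid
farthest_point_knots <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) return(seq_len(n))
  d0 <- (coords[, 1] - mean(coords[, 1]))^2 +
        (coords[, 2] - mean(coords[, 2]))^2
  sel <- integer(k)
  sel[1] <- which.min(d0)
  mind <- (coords[, 1] - coords[sel[1], 1])^2 +
          (coords[, 2] - coords[sel[1], 2])^2
  for (i in seq_len(k)[-1]) {
    sel[i] <- which.max(mind)
    di <- (coords[, 1] - coords[sel[i], 1])^2 +
          (coords[, 2] - coords[sel[i], 2])^2
    mind <- pmin(mind, di)
  }
  sort(sel)
}

#' Build a thin-plate regression spline basis
#'
#' Constructs the `n x K` design matrix `[1, x, y, b_4 ... b_K]` and the
#' matching `K x K` roughness penalty over standardized coordinates
#' (centered, scaled by root-mean-square radius, so the fit is invariant to
#' translation and uniform rescaling of the input units). The non-linear
#' columns come from the radial kernel `r^2 log r` evaluated against a
#' deterministic space-filling subset of `K` knots, reparametrized into the
#' null space of the thin-plate side conditions; the penalty is the kernel
#' Gram matrix in that parametrization (positive semi-definite, exactly
#' zero on affine surfaces). With `K = 3` the basis is the plain GLM design
#' `[1, x, y]` and the penalty is zero.
#'
#' @param coords two-column matrix (or data frame) of fiber coordinates.
#' @param K total basis dimension, `3 <= K <= n`.
#' @return An object of class `tprs_basis`: list with `design`, `penalty`,
#'   `K`, and the information needed to evaluate the basis at new
#'   coordinates (`center`, `scale`, `knots`, `Z`).
#' @export
build_tprs_basis <- function(coords, K) {
  coords <- as.matrix(coords[, 1:2])
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (K < 3) stop("K must be at least 3", call. = FALSE)
  if (K > n) stop("K (", K, ") exceeds the number of points (", n, ")",
                  call. = FALSE)
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    warning("duplicate coordinates: basis may be rank-deficient; ",
            "consider jittering", call. = FALSE)
  center <- colMeans(coords)
  cc <- sweep(coords, 2, center)
  scale <- sqrt(mean(cc[, 1]^2 + cc[, 2]^2))
  if (scale <= 0) stop("degenerate coordinates", call. = FALSE)
  sc <- cc / scale
  if (K == 3) {
    basis <- structure(list(design = cbind(1, sc), penalty = matrix(0, 3, 3),
                            K = 3L, center = center, scale = scale,
                            knots = NULL, Z = NULL),
                       class = "tprs_basis")
    colnames(basis$design) <- c("(Intercept)", "x", "y")
    return(basis)
  }
  kn_idx <- farthest_point_knots(sc, K)
  kn <- sc[kn_idx, , drop = FALSE]
  k <- nrow(kn)
  # side conditions: columns of T = [1, kx, ky]; delta must satisfy T'delta=0
  Tm <- cbind(1, kn)
  qrT <- qr(Tm)
  Z <- qr.Q(qrT, complete = TRUE)[, -(1:3), drop = FALSE]  # k x (k-3)
  Ekk <- tps_eta(as.matrix(stats::dist(kn, diag = TRUE, upper = TRUE)))
  P_core <- crossprod(Z, Ekk %*% Z)
  P_core <- (P_core + t(P_core)) / 2
  # clamp tiny negative eigenvalues from floating point (kernel is
  # conditionally positive definite on the constrained subspace)
  eg <- eigen(P_core, symmetric = TRUE)
  P_core <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  penalty <- matrix(0, K, K)
  penalty[4:K, 4:K] <- P_core
  basis <- structure(list(design = NULL, penalty = penalty, K = as.integer(K),
                          center = center, scale = scale, knots = kn, Z = Z),
                     class = "tprs_basis")
  basis$design <- evaluate_basis(basis, coords)
  basis
}

#' Evaluate a TPRS basis at new coordinates
#'
#' Reproduces the training design matrix exactly when evaluated at the
#' training coordinates.
#'
#' @param basis a `tprs_basis`.
#' @param coords two-column matrix of coordinates (original units).
#' @return An `nrow(coords) x K` design matrix.
#' @export
evaluate_basis <- function(basis, coords) {
  coords <- as.matrix(coords[, 1:2])
  sc <- sweep(coords, 2, basis$center) / basis$scale
  if (basis$K == 3L) {
    X <- cbind(1, sc)
    colnames(X) <- c("(Intercept)", "x", "y")
    return(X)
  }
  kn <- basis$knots
  D <- sqrt(outer(sc[, 1], kn[, 1], "-")^2 + outer(sc[, 2], kn[, 2], "-")^2)
  E <- tps_eta(D)
  X <- cbind(1, sc, E %*% basis$Z)
  colnames(X) <- c("(Intercept)", "x", "y",
                   paste0("tprs", seq_len(basis$K - 3L)))
  X
}

#' @export
print.tprs_basis <- function(x, ...) {
  cat(sprintf("Thin-plate regression spline basis: K = %d (%d knots)\n",
              x$K, if (is.null(x$knots)) 0L else nrow(x$knots)))
  invisible(x)
}

default_basis_dim <- function(n) min(30L, n %/% 4L) + 3L
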