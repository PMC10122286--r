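# Penalized logistic and multinomial GAMs over a TPRS basis: the log odds
# of a fiber being of a given type is a smooth surface in (x, y),
#   logit(p_i) = b0 + b1 x_i + b2 y_i + sum_{k>=4} b_k B_k(x_i, y_i),
# fitted by penalized IRLS maximizing l(beta) - (lambda/2) beta' S beta,
# with lambda chosen by a Laplace-approximate REML criterion (or GCV).

# penalized IRLS core for Bernoulli response
pirls_fit <- function(X, y, S, lambda, max_iter = 200, tol = 1e-7) {
  n <- nrow(X); K <- ncol(X)
  beta <- numeric(K)
  beta[1] <- stats::qlogis((sum(y) + 0.5) / (n + 1))
  pen <- lambda * S
  pen_loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE)) -
      0.5 * drop(crossprod(b, pen %*% b))
  }
  ll <- pen_loglik(beta)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X, X * w) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + diag(1e-8 * max(diag(H)), K)
      step <- solve(H, grad)
    }
    # step halving on the penalized log-likelihood
    t_ <- 1
    repeat {
      cand <- beta + t_ * step
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-8) { cand <- beta; ll_new <- ll; break }
    }
    beta <- cand
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol * (1 + abs(ll_new)) && it > 1) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X, X * w)
  H <- XtWX + pen
  edf <- sum(diag(solve(H, XtWX)))
  loglik <- sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
  list(beta = beta, fitted = mu, edf = edf, loglik = loglik,
       deviance = -2 * loglik, penalty = drop(crossprod(beta, S %*% beta)),
       H = H, XtWX = XtWX, converged = converged, iterations = it)
}

penalty_logdet_info <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > max(ev, 0) * 1e-10]
  list(rank = length(pos), logdet = sum(log(pos)))
}

# Laplace-approximate REML score (to be minimized) and deviance-based GCV
criterion_value <- function(fit, S, lambda, sinfo, n) {
  if (sinfo$rank == 0) return(fit$deviance)
  ldH <- 2 * sum(log(diag(chol(fit$H))))
  reml <- -fit$loglik + 0.5 * lambda * fit$penalty + 0.5 * ldH -
    0.5 * (sinfo$rank * log(lambda) + sinfo$logdet)
  reml
}

gcv_value <- function(fit, n) n * fit$deviance / (n - fit$edf)^2

#' Select the smoothing parameter
#'
#' Chooses `lambda` by minimizing the configured smoothness-selection
#' criterion -- a Laplace-approximate REML score (default) or deviance-based
#' GCV -- over a log-spaced grid refined by golden-section search. The
#' selection is deterministic given the data. If the criterion is monotone
#' over the search range, the boundary value is returned with a warning.
#'
#' @param y binary 0/1 response vector.
#' @param basis a [build_tprs_basis()] result.
#' @param criterion `"REML"` or `"GCV"`.
#' @param lambda_range log10 search range (default `c(-4, 8)`).
#' @return Selected `lambda` (scalar), with the criterion value as
#'   attribute `criterion_value`.
#' @export
select_lambda <- function(y, basis, criterion = c("REML", "GCV"),
                          lambda_range = c(-4, 8)) {
  criterion <- match.arg(criterion)
  X <- basis$design; S <- basis$penalty
  sinfo <- penalty_logdet_info(S)
  if (sinfo$rank == 0) return(structure(0, criterion_value = NA_real_))
  n <- nrow(X)
  score <- function(loglam) {
    lam <- 10^loglam
    fit <- pirls_fit(X, y, S, lam)
    if (criterion == "REML") criterion_value(fit, S, lam, sinfo, n)
    else gcv_value(fit, n)
  }
  grid <- seq(lambda_range[1], lambda_range[2], length.out = 17)
  vals <- vapply(grid, score, 0)
  best <- which.min(vals)
  if (best == 1L || best == length(grid)) {
    warning("criterion is monotone over the lambda search range; ",
            "returning boundary lambda", call. = FALSE)
    return(structure(10^grid[best], criterion_value = vals[best]))
  }
  # golden-section refinement inside the bracketing interval
  lo <- grid[best - 1]; hi <- grid[best + 1]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- score(c1); f2 <- score(c2)
  for (i in 1:30) {
    if (b - a < 1e-3) break
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- score(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- score(c2) }
  }
  loglam <- if (f1 < f2) c1 else c2
  structure(10^loglam, criterion_value = min(f1, f2))
}

#' Fit a logistic GAM for fiber-type probability
#'
#' Models the log odds of a fiber being fast as a smooth thin-plate spline
#' surface of its coordinates, maximizing the penalized Bernoulli
#' log-likelihood `l(beta) - (lambda/2) beta' S beta` by penalized IRLS.
#' The smoothing parameter can be fixed (`lambda = value`) or selected
#' automatically (`lambda = "auto"`, the default, via [select_lambda()]).
#' As `lambda -> Inf` the fit collapses to plain logistic regression on
#' `(x, y)`.
#'
#' @param section a [fiber_section].
#' @param fast_labels labels to treat as fast (see [encode_binary()]).
#' @param K basis dimension; default `min(30, floor(n/4)) + 3`.
#' @param lambda `"auto"` or a non-negative numeric value.
#' @param criterion smoothness-selection criterion for `"auto"`.
#' @param basis optional precomputed [build_tprs_basis()] (overrides `K`).
#' @return An object of class `gam_fit`: coefficients `beta`, `lambda`,
#'   `basis`, `edf`, `converged`, `criterion`, `criterion_value`, fitted
#'   probabilities, and the response used.
#' @export
fit_logistic_gam <- function(section, fast_labels, K = NULL,
                             lambda = "auto", criterion = c("REML", "GCV"),
                             basis = NULL) {
  criterion <- match.arg(criterion)
  labels <- encode_binary(section, fast_labels)
  y <- (labels$z + 1L) %/% 2L
  fit_logistic_gam_y(cbind(section$x, section$y), y, K = K, lambda = lambda,
                     criterion = criterion, basis = basis,
                     fast_labels = labels$fast_labels)
}

# core fitter on a bare 0/1 response (shared with the multinomial path)
fit_logistic_gam_y <- function(coords, y, K = NULL, lambda = "auto",
                               criterion = "REML", basis = NULL,
                               fast_labels = NULL) {
  n <- length(y)
  if (is.null(basis)) {
    if (is.null(K)) K <- default_basis_dim(n)
    if (n <= K) stop("need n > K (n=", n, ", K=", K, ")", call. = FALSE)
    basis <- build_tprs_basis(coords, K)
  }
  auto <- identical(lambda, "auto")
  if (auto) lambda <- select_lambda(y, basis, criterion)
  stopifnot(is.numeric(lambda), lambda >= 0)
  fit <- pirls_fit(basis$design, y, basis$penalty, as.numeric(lambda))
  if (!fit$converged)
    warning("penalized IRLS did not reach the gradient tolerance after ",
            fit$iterations, " iterations", call. = FALSE)
  structure(list(beta = fit$beta, lambda = as.numeric(lambda),
                 lambda_auto = auto, criterion = criterion,
                 criterion_value = attr(lambda, "criterion_value") %||% NA_real_,
                 basis = basis, edf = fit$edf, converged = fit$converged,
                 fitted = fit$fitted, y = y, deviance = fit$deviance,
                 loglik = fit$loglik, fast_labels = fast_labels),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("Logistic GAM (thin-plate spline surface)\n")
  cat(sprintf("  n = %d, K = %d, lambda = %.4g (%s), edf = %.2f\n",
              length(x$y), x$basis$K, x$lambda,
              if (x$lambda_auto) x$criterion else "fixed", x$edf))
  cat(sprintf("  deviance = %.2f, converged: %s\n", x$deviance, x$converged))
  invisible(x)
}

#' Predicted type probabilities at arbitrary coordinates
#'
#' @param object a `gam_fit`.
#' @param coords two-column matrix of coordinates; default the training
#'   coordinates.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.gam_fit <- function(object, coords = NULL, ...) {
  if (is.null(coords)) return(object$fitted)
  X <- evaluate_basis(object$basis, as.matrix(coords))
  stats::plogis(drop(X %*% object$beta))
}

#' Gridded probability surface
#'
#' Evaluates a fitted GAM on a regular grid over the boundary polygon's
#' bounding box, masking points outside the boundary: the probability map
#' of a fiber at each location being of the modeled type(s).
#'
#' @param fit a `gam_fit` or `multi_gam_fit`.
#' @param boundary a `boundary_polygon`.
#' @param resolution grid points per axis (default 100).
#' @return An object of class `probability_surface`: `grid_x`, `grid_y`
#'   (axis coordinates), `prob` (matrix, or named list of matrices for the
#'   multinomial fit; `NA` outside the mask), `mask` (logical matrix).
#' @export
predict_probability_grid <- function(fit, boundary, resolution = 100) {
  stopifnot(inherits(fit, c("gam_fit", "multi_gam_fit")))
  gx <- seq(min(boundary[, 1]), max(boundary[, 1]), length.out = resolution)
  gy <- seq(min(boundary[, 2]), max(boundary[, 2]), length.out = resolution)
  gg <- expand.grid(x = gx, y = gy)
  mask <- matrix(spatstat.geom::inside.owin(gg$x, gg$y,
                                            boundary_owin(boundary)),
                 nrow = resolution)
  if (inherits(fit, "gam_fit")) {
    p <- matrix(predict(fit, gg), nrow = resolution)
    p[!mask] <- NA_real_
    prob <- p
  } else {
    pr <- predict(fit, gg)
    prob <- lapply(seq_len(ncol(pr)), function(j) {
      p <- matrix(pr[, j], nrow = resolution)
      p[!mask] <- NA_real_
      p
    })
    names(prob) <- colnames(pr)
  }
  structure(list(grid_x = gx, grid_y = gy, prob = prob, mask = mask,
                 boundary = boundary),
            class = "probability_surface")
}

#' @export
print.probability_surface <- function(x, ...) {
  k <- if (is.list(x$prob)) length(x$prob) else 1L
  cat(sprintf("Probability surface: %d x %d grid, %d type(s), %.0f%% inside boundary\n",
              length(x$grid_x), length(x$grid_y), k, 100 * mean(x$mask)))
  invisible(x)
}

#' Export a probability surface as a data frame
#'
#' @param surface a `probability_surface`.
#' @param path optional CSV path.
#' @return Data frame with `grid_x`, `grid_y` and one probability column
#'   per type (rows outside the boundary dropped).
#' @export
surface_as_data_frame <- function(surface, path = NULL) {
  gg <- expand.grid(grid_x = surface$grid_x, grid_y = surface$grid_y)
  if (is.list(surface$prob)) {
    for (nm in names(surface$prob))
      gg[[paste0("prob_", nm)]] <- as.vector(surface$prob[[nm]])
  } else gg$prob <- as.vector(surface$prob)
  gg <- gg[as.vector(surface$mask), , drop = FALSE]
  if (!is.null(path)) { utils::write.csv(gg, path, row.names = FALSE); return(invisible(gg)) }
  gg
}

#' Fit a multinomial GAM for three or more fiber types
#'
#' Extends the logistic GAM to a categorical response: with `C` types and
#' the most frequent type as the reference, `C - 1` smooth log-odds
#' surfaces share one TPRS basis, each with its own smoothing parameter
#' (selected on the corresponding type-vs-reference subfit), and the
#' per-fiber probabilities follow from the softmax link, summing to one.
#' Fitted by full Newton iteration on the penalized multinomial
#' log-likelihood. With two types this reduces exactly to
#' [fit_logistic_gam()].
#'
#' @param section a [fiber_section] with >= 2 distinct types.
#' @param K basis dimension; reduced with a warning if a type has fewer
#'   than `K/2` fibers.
#' @param criterion smoothness-selection criterion.
#' @return An object of class `multi_gam_fit`: `types`, `reference`,
#'   `beta` (K x (C-1)), `lambda` (per surface), `basis`, `fitted`
#'   (n x C probabilities), `converged`.
#' @export
fit_multinomial_gam <- function(section, K = NULL,
                                criterion = c("REML", "GCV")) {
  criterion <- match.arg(criterion)
  tab <- sort(table(section$type), decreasing = TRUE)
  types <- names(tab)
  C <- length(types)
  if (C < 2) stop("need at least 2 fiber types", call. = FALSE)
  n <- nrow(section)
  if (is.null(K)) K <- default_basis_dim(n)
  small <- tab < 10
  if (any(small))
    warning("type(s) with < 10 fibers: ",
            paste(types[small], collapse = ", "),
            " (surface will be unstable)", call. = FALSE)
  if (any(tab < K / 2)) {
    K <- max(4L, as.integer(2 * min(tab)))
    warning("reducing K to ", K, " because a type has few fibers",
            call. = FALSE)
  }
  coords <- cbind(section$x, section$y)
  basis <- build_tprs_basis(coords, K)
  reference <- types[1]
  others <- types[-1]
  Y <- outer(section$type, types, "==") * 1  # n x C indicator
  # per-surface lambda from the type-vs-reference binary subfit
  sub <- lapply(others, function(tp) {
    idx <- section$type %in% c(tp, reference)
    bsub <- build_tprs_basis(coords[idx, , drop = FALSE],
                             min(K, sum(idx) - 1L))
    lam <- select_lambda((section$type[idx] == tp) * 1L, bsub, criterion)
    as.numeric(lam)
  })
  lambda <- setNames(vapply(sub, identity, 0), others)
  if (C == 2) {
    bf <- fit_logistic_gam_y(coords, drop(Y[, 2]), basis = basis,
                             lambda = lambda[[1]], criterion = criterion)
    fitted <- cbind(1 - bf$fitted, bf$fitted)
    colnames(fitted) <- types
    return(structure(list(types = types, reference = reference,
                          beta = matrix(bf$beta, ncol = 1,
                                        dimnames = list(NULL, others)),
                          lambda = lambda, basis = basis, fitted = fitted,
                          edf = bf$edf, converged = bf$converged),
                     class = "multi_gam_fit"))
  }
  X <- basis$design; S <- basis$penalty
  Cm1 <- C - 1L
  beta <- matrix(0, ncol(X), Cm1, dimnames = list(NULL, others))
  cls <- match(section$type, types)  # 1 = reference
  # penalized multinomial log-likelihood and derivatives
  loglik_grad_hess <- function(B, want_hess = TRUE) {
    eta <- X %*% B                       # n x (C-1)
    mx <- apply(cbind(0, eta), 1, max)
    em <- exp(eta - mx)
    e0 <- exp(-mx)
    denom <- e0 + rowSums(em)
    P <- em / denom                      # n x (C-1), prob of non-reference
    Pfull <- cbind(e0 / denom, P)
    ll <- sum(log(Pfull[cbind(seq_len(n), cls)]))
    pen <- 0
    for (c_ in seq_len(Cm1))
      pen <- pen + lambda[c_] * drop(crossprod(B[, c_], S %*% B[, c_]))
    grad <- vapply(seq_len(Cm1), function(c_)
      drop(crossprod(X, Y[, c_ + 1L] - P[, c_])) -
        lambda[c_] * drop(S %*% B[, c_]), numeric(ncol(X)))
    out <- list(ll = ll, pll = ll - pen / 2, grad = as.vector(grad), P = P)
    if (want_hess) {
      Kp <- ncol(X)
      H <- matrix(0, Kp * Cm1, Kp * Cm1)
      for (c_ in seq_len(Cm1)) for (d_ in seq_len(c_)) {
        w <- if (c_ == d_) P[, c_] * (1 - P[, c_]) else -P[, c_] * P[, d_]
        blk <- crossprod(X, X * w)
        if (c_ == d_) blk <- blk + lambda[c_] * S
        ri <- (c_ - 1L) * Kp + seq_len(Kp); ci <- (d_ - 1L) * Kp + seq_len(Kp)
        H[ri, ci] <- blk; H[ci, ri] <- t(blk)
      }
      out$H <- H
    }
    out
  }
  cur <- loglik_grad_hess(beta)
  converged <- FALSE
  for (it in 1:100) {
    step <- tryCatch(solve(cur$H, cur$grad), error = function(e) NULL)
    if (is.null(step))
      step <- solve(cur$H + diag(1e-8 * max(diag(cur$H)), nrow(cur$H)),
                    cur$grad)
    t_ <- 1
    repeat {
      Bnew <- beta + matrix(t_ * step, ncol = Cm1)
      new <- loglik_grad_hess(Bnew, want_hess = FALSE)
      if (is.finite(new$pll) && new$pll >= cur$pll - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-8) { Bnew <- beta; new <- cur; break }
    }
    beta <- Bnew
    gn <- sqrt(sum(new$grad^2))
    cur <- loglik_grad_hess(beta)
    if (gn < 1e-6 * (1 + abs(cur$pll))) { converged <- TRUE; break }
  }
  if (!converged)
    warning("multinomial Newton did not reach the gradient tolerance",
            call. = FALSE)
  P <- cur$P
  fitted <- cbind(1 - rowSums(P), P)
  colnames(fitted) <- types
  structure(list(types = types, reference = reference, beta = beta,
                 lambda = lambda, basis = basis, fitted = fitted,
                 converged = converged),
            class = "multi_gam_fit")
}

#' @export
print.multi_gam_fit <- function(x, ...) {
  cat("Multinomial GAM:", length(x$types), "types (reference:",
      x$reference, ")\n")
  cat("  lambda:", paste(sprintf("%s=%.3g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
predict.multi_gam_fit <- function(object, coords = NULL, ...) {
  if (is.null(coords)) return(object$fitted)
  X <- evaluate_basis(object$basis, as.matrix(coords))
  eta <- X %*% object$beta
  mx <- apply(cbind(0, eta), 1, max)
  em <- exp(eta - mx); e0 <- exp(-mx)
  denom <- e0 + rowSums(em)
  out <- cbind(e0 / denom, em / denom)
  colnames(out) <- object$types
  out
}
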