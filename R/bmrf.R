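# Binary Markov random field (autologistic model) for fiber spins:
#   Pr(Z = z) propto exp{ alpha * sum_i z_i + beta * sum_{i~j} z_i z_j }
# alpha governs the slow/fast balance, beta the like-type interaction.
# Estimation is by maximum pseudolikelihood via the logistic-regression
# reduction: Pr(Z_i = z | rest) = plogis(2 z (alpha + beta S_i)), so
# regressing (z+1)/2 on S_i gives coefficients (2 alpha, 2 beta).

adjacency_sparse <- function(network) {
  e <- network$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(network$n, network$n))
}

neighbor_spin_sums <- function(network, z) {
  if (!network$m) return(numeric(network$n))
  as.numeric(adjacency_sparse(network) %*% as.numeric(z))
}

#' Log-pseudolikelihood of the binary Markov random field
#'
#' Sum over fibers of the log conditional probability of the observed spin
#' given its neighbors, `sum_i log plogis(2 z_i (alpha + beta S_i))` with
#' `S_i` the sum of neighboring spins. Numerically stabilized through the
#' log-logistic form (no overflow for extreme parameters).
#'
#' @param network a `neighbor_network`.
#' @param labels a `binary_labels` object.
#' @param alpha,beta model parameters.
#' @return Scalar log-pseudolikelihood.
#' @export
log_pseudolikelihood <- function(network, labels, alpha, beta) {
  check_shapes(network, labels)
  stopifnot(is.finite(alpha), is.finite(beta))
  z <- as.numeric(labels$z)
  S <- neighbor_spin_sums(network, z)
  sum(stats::plogis(2 * z * (alpha + beta * S), log.p = TRUE))
}

#' Fit the binary Markov random field by maximum pseudolikelihood
#'
#' Maximizes the pseudolikelihood through its logistic-regression
#' reduction: `(z_i + 1)/2 ~ S_i` with a logit link, whose intercept and
#' slope are `2 alpha` and `2 beta`. The fit is deterministic. Under
#' perfect separation (e.g. an exact chequerboard) the estimates are
#' bounded at `|alpha|, |beta| <= 10` and a warning is raised.
#'
#' @inheritParams log_pseudolikelihood
#' @param bound parameter bound applied under separation (default 10).
#' @return An object of class `bmrf_fit` with elements `alpha`, `beta`,
#'   `logpl` (log-pseudolikelihood at the optimum), `converged`, `n`, `m`.
#' @export
fit_bmrf <- function(network, labels, bound = 10) {
  check_shapes(network, labels)
  if (labels$n_slow == 0 || labels$n_fast == 0)
    stop("both types must be present", call. = FALSE)
  if (network$m < 1) stop("network has no edges", call. = FALSE)
  z <- as.numeric(labels$z)
  S <- neighbor_spin_sums(network, z)
  y <- (labels$z + 1L) %/% 2L
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ S, family = stats::binomial(),
               control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  alpha <- unname(coef(fit)[1]) / 2
  beta <- unname(coef(fit)[2]) / 2
  converged <- fit$converged && !sep
  if (!converged || abs(alpha) > bound || abs(beta) > bound) {
    # separation / runaway estimates: bounded direct maximization
    warning("pseudolikelihood maximum is degenerate (separation); ",
            "parameters bounded at |", bound, "|", call. = FALSE)
    obj <- function(par)
      -sum(stats::plogis(2 * z * (par[1] + par[2] * S), log.p = TRUE))
    opt <- stats::optim(c(0, 0), obj, method = "L-BFGS-B",
                        lower = c(-bound, -bound), upper = c(bound, bound))
    alpha <- opt$par[1]; beta <- opt$par[2]
    converged <- FALSE
  }
  structure(list(alpha = alpha, beta = beta,
                 logpl = log_pseudolikelihood(network,
                                              binary_labels_from_z(labels$z),
                                              alpha, beta),
                 converged = converged, n = network$n, m = network$m,
                 n_slow = labels$n_slow, n_fast = labels$n_fast,
                 envelope = NULL, n_perm = NULL, seed = NULL,
                 verdict = NULL),
            class = "bmrf_fit")
}

#' Permutation envelope for the interaction parameter
#'
#' 2.5th/97.5th percentiles (linear interpolation) of the pseudolikelihood
#' estimate of `beta` over random relabelings with fixed type counts. An
#' observed `beta` above the envelope indicates like-type attraction, below
#' it repulsion. A permutation whose fast Newton fit fails to converge is
#' redrawn (up to 10 retries) and the event is recorded.
#'
#' @inheritParams log_pseudolikelihood
#' @param n_perm number of permutations (>= 199; default 999).
#' @param seed integer seed.
#' @return Named numeric vector `c(lo, hi)` with attributes `n_perm`,
#'   `seed`, `n_redrawn`.
#' @export
beta_permutation_envelope <- function(network, labels, n_perm = 999,
                                      seed = NULL) {
  check_shapes(network, labels)
  if (n_perm < 199) stop("n_perm must be at least 199", call. = FALSE)
  A <- adjacency_sparse(network)
  redrawn <- 0L
  betas <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      co <- NULL
      for (try in seq_len(11L)) {
        zp <- sample(labels$z)
        S <- as.numeric(A %*% zp)
        co <- .cpp_logit2_newton(S, (zp + 1L) %/% 2L, 1e-10, 50L, 20)
        if (co[3] == 1) return(co[2] / 2)
        redrawn <<- redrawn + 1L
      }
      co[2] / 2  # last resort: bounded estimate from final try
    }, 0)
  })
  env <- stats::quantile(betas, c(0.025, 0.975), names = FALSE, type = 7)
  structure(c(lo = env[1], hi = env[2]), n_perm = n_perm, seed = seed,
            n_redrawn = redrawn, class = "beta_envelope")
}

#' Fit the BMRF with a permutation envelope and verdict
#'
#' Convenience wrapper around [fit_bmrf()] and
#' [beta_permutation_envelope()], attaching the randomness verdict:
#' `attraction` if `beta` exceeds the envelope, `repulsion` if below,
#' `random` otherwise.
#'
#' @inheritParams beta_permutation_envelope
#' @return A `bmrf_fit` with `envelope`, `n_perm`, `seed` and `verdict`
#'   fields populated.
#' @export
fit_bmrf_with_envelope <- function(network, labels, n_perm = 999,
                                   seed = NULL) {
  fit <- fit_bmrf(network, labels)
  env <- beta_permutation_envelope(network, labels, n_perm = n_perm,
                                   seed = seed)
  fit$envelope <- c(lo = unname(env["lo"]), hi = unname(env["hi"]))
  fit$n_perm <- n_perm
  fit$seed <- seed
  fit$verdict <- if (fit$beta > fit$envelope["hi"]) "attraction"
                 else if (fit$beta < fit$envelope["lo"]) "repulsion"
                 else "random"
  fit
}

#' @export
print.bmrf_fit <- function(x, ...) {
  cat("Binary Markov random field (maximum pseudolikelihood)\n")
  cat(sprintf("  alpha = %.4g  (balance: %d slow, %d fast)\n",
              x$alpha, x$n_slow, x$n_fast))
  cat(sprintf("  beta  = %.4g  (interaction)\n", x$beta))
  if (!is.null(x$envelope))
    cat(sprintf("  envelope for beta = 0: (%.4g, %.4g)  [n_perm=%d] -> %s\n",
                x$envelope[1], x$envelope[2], x$n_perm, x$verdict))
  if (!x$converged) cat("  note: degenerate fit, parameters bounded\n")
  invisible(x)
}
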