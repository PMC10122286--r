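coords_for <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n, 0, 10), runif(n, 0, 7))
}

test_that("TPRS basis has the affine null space and reproduces itself", {
  xy <- coords_for(50, 71)
  # K = 3 is exactly the GLM design with zero penalty
  b3 <- build_tprs_basis(xy, 3)
  expect_equal(unname(b3$design[, 1]), rep(1, 50))
  expect_equal(b3$penalty, matrix(0, 3, 3))
  # evaluation at training coordinates reproduces the design
  b20 <- build_tprs_basis(xy, 20)
  expect_equal(evaluate_basis(b20, xy), b20$design, tolerance = 1e-10)
  # penalty vanishes on affine surfaces (null space) and is psd
  for (r in 1:5) {
    set.seed(700 + r)
    beta_aff <- c(rnorm(3), rep(0, 17))
    expect_equal(drop(beta_aff %*% b20$penalty %*% beta_aff), 0)
    beta_any <- rnorm(20)
    expect_gte(drop(beta_any %*% b20$penalty %*% beta_any), -1e-10)
  }
  expect_error(build_tprs_basis(xy, 60), "exceeds")
})

test_that("large lambda collapses the GAM to plain logistic regression", {
  xy <- coords_for(400, 72)
  set.seed(73)
  p <- plogis(-0.5 + 0.25 * xy[, 1] - 0.15 * xy[, 2])
  sec <- fiber_section(xy[, 1], xy[, 2],
                       ifelse(runif(400) < p, "fast", "slow"))
  fit <- fit_logistic_gam(sec, "fast", K = 20, lambda = 1e9)
  ref <- glm(I(sec$type == "fast") ~ x + y, family = binomial(),
             data = data.frame(x = sec$x, y = sec$y))
  expect_equal(unname(fitted(ref)), unname(fit$fitted), tolerance = 1e-4)
  expect_equal(fit$edf, 3, tolerance = 1e-3)
  # edf decreases with lambda and stays within [3, K]
  edfs <- vapply(c(0.01, 1, 100, 1e6),
                 function(l) fit_logistic_gam(sec, "fast", K = 20,
                                              lambda = l)$edf, 0)
  expect_true(all(diff(edfs) < 1e-8))
  expect_true(all(edfs >= 3 - 1e-6 & edfs <= 20 + 1e-6))
})

test_that("swapped labels give the exactly complementary surface", {
  xy <- coords_for(300, 74)
  set.seed(75)
  sec <- fiber_section(xy[, 1], xy[, 2],
                       sample(c("I", "II"), 300, TRUE))
  f1 <- fit_logistic_gam(sec, "II", K = 15, lambda = 2)
  f2 <- fit_logistic_gam(sec, "I", K = 15, lambda = 2)
  expect_equal(f2$fitted, 1 - f1$fitted, tolerance = 1e-10)
  # surfaces invariant under uniform rescaling of the coordinates
  sec_sc <- fiber_section(250 * sec$x + 3, 250 * sec$y - 9, sec$type)
  f3 <- fit_logistic_gam(sec_sc, "II", K = 15, lambda = 2)
  expect_equal(f3$fitted, f1$fitted, tolerance = 1e-6)
})

test_that("lambda selection reacts to signal and is deterministic", {
  pts <- generate_lattice_section(32, 32, 0.3, seed = 76)
  # pure noise: selected smoothing drives the fit to (near) the plane
  noise <- simulate_surface_section(pts, surface_constant(0.5), seed = 77)
  suppressWarnings({
    lam_noise <- select_lambda((noise$type == "fast") * 1L,
                               build_tprs_basis(cbind(noise$x, noise$y), 23))
    fit_noise <- fit_logistic_gam(noise, "fast", K = 23)
  })
  expect_lte(fit_noise$edf, 4 + 1)
  # strong smooth signal: interior lambda, clearly flexible fit
  f <- function(x, y) plogis(2.2 * sin(0.45 * x) * cos(0.3 * y))
  sig <- simulate_surface_section(pts, f, seed = 78)
  fit_sig <- fit_logistic_gam(sig, "fast", K = 23)
  expect_gt(fit_sig$edf, 4)
  lam1 <- select_lambda((sig$type == "fast") * 1L,
                        build_tprs_basis(cbind(sig$x, sig$y), 23))
  lam2 <- select_lambda((sig$type == "fast") * 1L,
                        build_tprs_basis(cbind(sig$x, sig$y), 23))
  expect_identical(as.numeric(lam1), as.numeric(lam2))
  # penalized deviance at the selected lambda beats the pure plane
  plane <- fit_logistic_gam(sig, "fast", K = 23, lambda = 1e9)
  expect_lte(fit_sig$deviance, plane$deviance)
})

test_that("fitted smooth surfaces recover the generating probability field", {
  pts <- generate_lattice_section(45, 45, 0.3, seed = 79)
  maes <- vapply(1:5, function(r) {
    sec <- simulate_surface_section(pts, surface_linear(0.1, 0.9, "x"),
                                    seed = 790 + r)
    fit <- suppressWarnings(fit_logistic_gam(sec, "fast"))
    mean(abs(fit$fitted - attr(sec, "prob_fast")))
  }, 0)
  expect_lt(mean(maes), 0.05)
  # flat p = 0.4 field: fitted probabilities stay in a tight band
  flat <- simulate_surface_section(pts, surface_constant(0.4), seed = 80)
  fit_flat <- suppressWarnings(fit_logistic_gam(flat, "fast"))
  expect_true(all(fit_flat$fitted > 0.3 & fit_flat$fitted < 0.5))
})

test_that("our penalized fit tracks the mgcv reference on the same data", {
  pts <- generate_lattice_section(35, 35, 0.3, seed = 81)
  f <- function(x, y) plogis(1.2 * cos(0.25 * x) + 0.8 * sin(0.2 * y))
  sec <- simulate_surface_section(pts, f, seed = 82)
  fit <- fit_logistic_gam(sec, "fast")
  ref <- mgcv::gam(I(type == "fast") ~ s(x, y, k = fit$basis$K),
                   family = binomial(), data = sec, method = "REML")
  expect_lt(mean(abs(fit$fitted - fitted(ref))), 0.05)
})

test_that("probability grids respect the mask, range and training fit", {
  pts <- generate_lattice_section(25, 25, 0.3, seed = 83)
  sec <- simulate_surface_section(pts, surface_radial(0.2, 0.8), seed = 84)
  fit <- suppressWarnings(fit_logistic_gam(sec, "fast"))
  # prediction at training coordinates equals in-sample fit
  expect_equal(predict(fit, cbind(sec$x, sec$y)), fit$fitted,
               tolerance = 1e-10)
  bnd <- boundary_polygon(sec)
  surf <- predict_probability_grid(fit, bnd, resolution = 50)
  inside <- surf$prob[surf$mask]
  expect_true(all(inside >= 0 & inside <= 1))
  expect_true(all(is.na(surf$prob[!surf$mask])))
  # radial pattern: outer band has higher fast probability than the center
  r <- sqrt(outer((surf$grid_x - mean(sec$x))^2,
                  (surf$grid_y - mean(sec$y))^2, "+"))
  rmax <- max(r[surf$mask])
  expect_gt(mean(surf$prob[surf$mask & r > 0.8 * rmax], na.rm = TRUE),
            mean(surf$prob[surf$mask & r < 0.2 * rmax], na.rm = TRUE))
  # intercept-only surface is flat at plogis(beta0)
  fit0 <- fit_logistic_gam(sec, "fast", K = 3, lambda = 0)
  fit0$beta[2:3] <- 0
  surf0 <- predict_probability_grid(fit0, bnd, resolution = 20)
  expect_equal(range(surf0$prob, na.rm = TRUE),
               rep(unname(plogis(fit0$beta[1])), 2), tolerance = 1e-12)
})

test_that("multinomial surfaces sum to one and reduce to the binary fit", {
  pts <- generate_lattice_section(30, 30, 0.3, seed = 85)
  # three types along a gradient
  xs <- (pts$x - min(pts$x)) / diff(range(pts$x))
  set.seed(86)
  pI <- 0.15 + 0.25 * xs; pIIa <- 0.45 - 0.2 * xs
  u <- runif(nrow(pts))
  ty <- ifelse(u < pI, "I", ifelse(u < pI + pIIa, "IIa", "IIb"))
  sec <- fiber_section(pts$x, pts$y, ty)
  mf <- suppressWarnings(fit_multinomial_gam(sec))
  expect_equal(rowSums(mf$fitted), rep(1, nrow(sec)), tolerance = 1e-10)
  grid <- cbind(runif(200, min(sec$x), max(sec$x)),
                runif(200, min(sec$y), max(sec$y)))
  expect_equal(rowSums(predict(mf, grid)), rep(1, 200), tolerance = 1e-10)
  # two classes: identical to the binary logistic GAM
  sec2 <- fiber_section(sec$x, sec$y, ifelse(sec$type == "I", "I", "II"))
  mf2 <- suppressWarnings(fit_multinomial_gam(sec2))
  bin <- suppressWarnings(
    fit_logistic_gam(sec2, "I", basis = mf2$basis,
                     lambda = unname(mf2$lambda["I"])))
  expect_equal(unname(mf2$beta[, 1]), unname(bin$beta), tolerance = 1e-6)
  # collapse consistency: binary I-vs-rest surface close to multinomial P(I)
  bin_auto <- suppressWarnings(fit_logistic_gam(sec2, "I"))
  expect_lt(mean(abs(bin_auto$fitted - mf$fitted[, "I"])), 0.05)
})
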