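test_that("direct projection implements -kBT log(k_i/k0) with anchoring", {
  # uniform occupancy: dG identically zero
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  prof <- direct_projection(matrix(x, ncol = 1), n_bins = 10,
                            temperature = 310, range = list(c(0, 1)))
  expect_true(all(abs(prof$dG) < 1e-12))

  # two bins with counts 100 and 10 at 310 K
  x <- c(rep(0.25, 100), rep(0.75, 10))
  prof <- direct_projection(matrix(x, ncol = 1), n_bins = 2,
                            temperature = 310, range = list(c(0, 1)))
  expect_equal(min(prof$dG), 0)
  expect_equal(max(prof$dG), -kB * 310 * log(0.1), tolerance = 1e-12)

  # empty bins are flagged Inf, never 0
  x <- c(rep(0.1, 5), rep(0.9, 5))
  prof <- direct_projection(matrix(x, ncol = 1), n_bins = 5,
                            temperature = 310, range = list(c(0, 1)))
  expect_equal(sum(!is.finite(prof$dG)), 3)

  # all-identical samples with >1 bin: one occupied bin
  prof <- direct_projection(matrix(rep(1.3, 50), ncol = 1), n_bins = 4,
                            temperature = 310)
  expect_equal(sum(is.finite(prof$dG)), 1)
  expect_equal(min(prof$dG), 0)

  expect_error(direct_projection(matrix(numeric(0), ncol = 1)), "empty")
})

test_that("occupancy ordering and temperature scaling behave", {
  x <- c(rep(0.1, 50), rep(0.3, 25), rep(0.5, 10), rep(0.7, 2))
  p1 <- direct_projection(matrix(x, ncol = 1), n_bins = 4,
                          temperature = 310, range = list(c(0, 0.8)))
  expect_true(all(diff(p1$dG) > 0))      # monotone counts -> monotone dG
  p2 <- direct_projection(matrix(x, ncol = 1), n_bins = 4,
                          temperature = 620, range = list(c(0, 0.8)))
  expect_equal(p2$dG, 2 * p1$dG, tolerance = 1e-12)
})

test_that("auto bin count is ceiling(sqrt(N))", {
  set.seed(2)
  x <- matrix(runif(137), ncol = 1)
  prof <- direct_projection(x, temperature = 310)
  expect_equal(length(prof$dG), ceiling(sqrt(137)))
})

test_that("2D projections bin independently per axis", {
  set.seed(5)
  v <- cbind(a = runif(400), b = runif(400, 10, 20))
  prof <- direct_projection(v, axes = c("a", "b"), n_bins = c(5, 8),
                            temperature = 310)
  expect_equal(dim(prof$dG), c(5, 8))
  expect_equal(sum(prof$counts), 400)
  expect_equal(min(prof$dG), 0)
})

test_that("equilibration discard trims by time", {
  s <- cv_series(seq(0.1, 10, by = 0.1), rnorm(100), 310, "x")
  w <- umbrella_window(s, 0, 150)
  w2 <- equilibration_discard(w, 2)
  # frames with time < 2 ps removed; the 2.0 ps frame itself is retained
  expect_equal(n_frames(w2$series), 81)
  expect_equal(diff(range(w2$series$times)), 8)  # 8 ps retained
  expect_true(all(w2$series$times >= 2))
  expect_identical(equilibration_discard(w, 0), w)
  expect_error(equilibration_discard(w, 11), "empty")
})

test_that("WHAM with null bias equals the pooled direct histogram", {
  set.seed(31)
  s1 <- cv_series(1:300, rnorm(300, 0, 0.4), 310, "x")
  s2 <- cv_series(1:200, rnorm(200, 0.5, 0.4), 310, "x")
  w <- list(umbrella_window(s1, 0, 0), umbrella_window(s2, 0.5, 0))
  wh <- wham_solve(w, n_bins = 24)
  pooled <- direct_projection(matrix(c(s1$values, s2$values), ncol = 1),
                              n_bins = 24, temperature = 310,
                              range = list(range(c(s1$values, s2$values))))
  expect_identical(as.numeric(rowSums(wh$solution$counts)),
                   as.numeric(pooled$counts))
  fin <- is.finite(pooled$dG)
  expect_lt(max(abs(wh$profile$dG[fin] - pooled$dG[fin])), 1e-9)

  # single window, zero bias: same reduction
  wh1 <- wham_solve(w[1], n_bins = 10)
  d1 <- direct_projection(matrix(s1$values, ncol = 1), n_bins = 10,
                          temperature = 310)
  expect_lt(max(abs(wh1$profile$dG - d1$dG)), 1e-9)
})

test_that("WHAM recovers a harmonic PMF with the generating curvature", {
  pot <- potential_spec("harmonic", list(kappa = 5, center = 0))
  ws <- generate_umbrella_set(pot, centers = seq(-1, 1, by = 0.1),
                              force_constant = 100,
                              steps_per_window = 4000, seed = 13, dt = 5e-4)
  prof <- wham_solve(ws, n_bins = 80, range = c(-1, 1))$profile
  x <- prof$centers[[1]]
  fit <- lm(prof$dG ~ I(x^2 / 2))
  expect_lt(abs(coef(fit)[2] / 5 - 1), 0.10)
})

test_that("wham_solve matches the brute-force fixed point on small instances", {
  set.seed(41)
  for (case in 1:3) {
    nw <- sample(1:3, 1)
    centers <- sort(runif(nw, -0.5, 0.5))
    ws <- lapply(seq_len(nw), function(j) {
      n <- sample(20:50, 1)
      umbrella_window(cv_series(1:n, rnorm(n, centers[j], 0.3), 310, "x"),
                      centers[j], 20)
    })
    nb <- sample(5:10, 1)
    wh <- wham_solve(ws, n_bins = nb, tolerance = 1e-13,
                     max_iter = 5e5)
    beta <- 1 / (kB * 310)
    U <- vapply(ws, function(w) {
      0.5 * w$force_constant * (wh$solution$centers - w$center)^2
    }, numeric(nb))
    ref <- oracle_wham_bruteforce(matrix(wh$solution$counts, ncol = nw),
                                  wh$solution$N, matrix(U, ncol = nw), beta)
    expect_lt(max(abs(wh$solution$F - ref$F)), 1e-8)
    expect_lt(max(abs(wh$solution$mass - ref$rho)), 1e-8)
  }
})

test_that("disconnected window support is detected", {
  s1 <- cv_series(1:50, rnorm(50, -2, 0.05), 310, "x")
  s2 <- cv_series(1:50, rnorm(50, 2, 0.05), 310, "x")
  w <- list(umbrella_window(s1, -2, 150), umbrella_window(s2, 2, 150))
  expect_warning(wh <- wham_solve(w, n_bins = 50), "disconnected")
  expect_true(wh$solution$disconnected)
})

test_that("conformation weights reduce to uniform under zero bias", {
  set.seed(55)
  s1 <- cv_series(1:60, rnorm(60), 310, "x")
  w <- list(umbrella_window(s1, 0, 0))
  wh <- wham_solve(w, n_bins = 8)
  cw <- conformation_weights(w, wh$solution)
  expect_equal(cw$weights, rep(1 / 60, 60), tolerance = 1e-12)
  expect_equal(sum(cw$weights), 1, tolerance = 1e-10)

  s2 <- cv_series(1:40, rnorm(40, 0.5), 310, "x")
  w2 <- list(umbrella_window(s1, 0, 0), umbrella_window(s2, 0, 0))
  wh2 <- wham_solve(w2, n_bins = 8)
  cw2 <- conformation_weights(w2, wh2$solution)
  expect_equal(cw2$weights, rep(1 / 100, 100), tolerance = 1e-12)

  # provenance mismatch is refused
  expect_error(conformation_weights(w, wh2$solution), "match")
})

test_that("binned weights reproduce the WHAM density algebraically", {
  dw <- potential_spec("double_well", list(barrier = 3,
                                           half_separation = 1))
  ws <- generate_umbrella_set(dw, centers = seq(-1.2, 1.2, by = 0.15),
                              force_constant = 100,
                              steps_per_window = 1500, seed = 17, dt = 5e-4)
  wh <- wham_solve(ws, n_bins = 60, tolerance = 1e-12)
  cw <- conformation_weights(ws, wh$solution, at = "bin_center")
  acc <- vapply(seq_along(wh$solution$centers), function(m) {
    e <- wh$solution$edges
    sum(cw$weights[cw$x > e[m] & cw$x <= e[m + 1] |
                     (m == 1 & cw$x == e[1])])
  }, numeric(1))
  expect_lt(max(abs(acc - wh$solution$mass)), 1e-6)
})

test_that("reweighted projection degenerates correctly", {
  set.seed(23)
  x <- matrix(rnorm(500), ncol = 1)
  u <- rep(1 / 500, 500)
  expect_lt(max(abs(reweighted_projection(x, u, n_bins = 12,
                                          temperature = 310)$dG -
                    direct_projection(x, n_bins = 12,
                                      temperature = 310)$dG)), 1e-12)
  w <- numeric(500); w[17] <- 1
  prof <- reweighted_projection(x, w, n_bins = 12, temperature = 310)
  expect_equal(sum(prof$dG == 0), 1)
  expect_equal(sum(!is.finite(prof$dG)), 11)
})

test_that("convergence deviation is exactly zero on duplicated data", {
  pattern <- c(-0.2, -0.1, 0, 0.1, 0.2, 0.05, -0.05, 0.15)
  s <- cv_series(seq_along(rep(pattern, 4)), rep(pattern, 4), 310, "x")
  w <- list(umbrella_window(s, 0, 0))
  cc <- convergence_check(w, "direct", n_blocks = 4, n_bins = 6)
  expect_equal(cc$deviations, rep(0, 3))
  expect_true(cc$converged)
  cr <- convergence_check(w, "reverse", n_blocks = 4, n_bins = 6)
  expect_equal(cr$deviations, rep(0, 3))
})

test_that("tst_convert implements the Eyring relation", {
  pref <- tst_convert(0, "barrier_to_rate", 310)
  expect_equal(pref, kB * 310 / planck_h, tolerance = 1e-12)
  expect_equal(pref, 6.46e12, tolerance = 0.005)
  back <- tst_convert(tst_convert(14.4, "barrier_to_rate", 310),
                      "rate_to_barrier", 310)
  expect_equal(back, 14.4, tolerance = 1e-10)
  b <- c(5, 10, 15)
  expect_true(all(diff(tst_convert(b, "barrier_to_rate", 310)) < 0))
  expect_error(tst_convert(-1, "rate_to_barrier", 310), "positive")
})

test_that("profiles are invariant to a constant shift of window offsets", {
  # gauge invariance: adding a constant to all F_j leaves the density
  # unchanged after normalization
  set.seed(77)
  ws <- generate_umbrella_set(
    potential_spec("harmonic", list(kappa = 5, center = 0)),
    centers = seq(-0.4, 0.4, by = 0.1), force_constant = 100,
    steps_per_window = 500, seed = 3, dt = 5e-4)
  wh <- wham_solve(ws, n_bins = 30)
  beta <- 1 / (kB * 310)
  U <- vapply(ws, function(w) {
    0.5 * w$force_constant * (wh$solution$centers - w$center)^2
  }, numeric(30))
  dens <- function(f) {
    r <- rowSums(wh$solution$counts) /
      as.vector(exp(-beta * U) %*% (wh$solution$N * exp(beta * f)))
    r / sum(r)
  }
  expect_equal(dens(wh$solution$F), dens(wh$solution$F + 3.21),
               tolerance = 1e-12)
  expect_equal(min(wh$profile$dG[is.finite(wh$profile$dG)]), 0)
})
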