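# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (explicit loops, quadrature, grid search) and share no
# code with the implementation paths they check.

# numeric Boltzmann CDF of a 1D potential on its domain
oracle_boltzmann_cdf <- function(pot, temperature = 310, n_grid = 4001) {
  xs <- seq(pot$domain[1], pot$domain[2], length.out = n_grid)
  w <- exp(-potential_energy(pot, xs) / (kB * temperature))
  dx <- diff(xs)
  cum <- c(0, cumsum(dx * (w[-1] + w[-n_grid]) / 2))
  cum <- cum / cum[n_grid]
  function(x) stats::approx(xs, cum, xout = x, rule = 2)$y
}

# brute-force WHAM fixed point: plain loops over bins and windows
oracle_wham_bruteforce <- function(counts, N, U, beta, tol = 1e-12,
                                   max_iter = 200000) {
  nb <- nrow(counts); nw <- ncol(counts)
  f <- rep(0, nw)
  for (iter in seq_len(max_iter)) {
    rho <- numeric(nb)
    for (m in seq_len(nb)) {
      num <- 0; den <- 0
      for (j in seq_len(nw)) {
        num <- num + counts[m, j]
        den <- den + N[j] * exp(-beta * (U[m, j] - f[j]))
      }
      rho[m] <- num / den
    }
    fn <- numeric(nw)
    for (j in seq_len(nw)) {
      s <- 0
      for (m in seq_len(nb)) s <- s + rho[m] * exp(-beta * U[m, j])
      fn[j] <- -log(s) / beta
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  rho <- numeric(nb)
  for (m in seq_len(nb)) {
    den <- 0
    for (j in seq_len(nw)) den <- den + N[j] * exp(-beta * (U[m, j] - f[j]))
    rho[m] <- sum(counts[m, ]) / den
  }
  list(F = f, rho = rho / sum(rho))
}

# O(n^2) reference Gromos clustering on a precomputed distance matrix
oracle_gromos <- function(dm, cutoff) {
  n <- nrow(dm)
  assignment <- rep(NA_integer_, n)
  centroids <- integer(0)
  cl <- 0
  while (anyNA(assignment)) {
    cl <- cl + 1
    best <- -1; best_i <- NA
    for (i in seq_len(n)) {
      if (!is.na(assignment[i])) next
      cnt <- 0
      for (j in seq_len(n)) {
        if (is.na(assignment[j]) && dm[i, j] <= cutoff) cnt <- cnt + 1
      }
      if (cnt > best) { best <- cnt; best_i <- i }
    }
    for (j in seq_len(n)) {
      if (is.na(assignment[j]) && dm[best_i, j] <= cutoff) assignment[j] <- cl
    }
    centroids[cl] <- best_i
  }
  list(assignment = as.integer(assignment),
       centroids = as.integer(centroids))
}

# rotation-grid + local-refinement oracle for the minimal RMSd over proper
# rotations (independent of the SVD solution)
oracle_min_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(sum((a %*% t(rotmat(ang)) - b)^2) / nrow(a))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (g1 in grid) for (g2 in grid) for (g3 in grid) {
    v <- obj(c(g1, g2, g3))
    if (v < best) { best <- v; best_ang <- c(g1, g2, g3) }
  }
  stats::optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# small helpers for building conformation sets
perturbed_frames <- function(base, n, sd, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base + matrix(rnorm(length(base), sd = sd), nrow(base), 3)
  })
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# the criterion-1 synthetic world, shared by several acceptance checks
acceptance_double_well <- function() {
  potential_spec("double_well", list(barrier = 5, half_separation = 1))
}
acceptance_umbrella_set <- function(steps_per_window = 20000, seed = 7) {
  generate_umbrella_set(acceptance_double_well(),
                        centers = seq(-1.25, 1.25, by = 0.1),
                        force_constant = 150,
                        steps_per_window = steps_per_window,
                        seed = seed, dt = 5e-4)
}
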