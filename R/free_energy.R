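#' Binned Gibbs-energy profile
#'
#' A free-energy profile over 1 or 2 binned coordinates. The minimum finite
#' ΔG is anchored at exactly zero (the most probable bin); empty bins carry
#' `Inf` as an explicit undefined marker, never zero.
#'
#' `profile_from_mass()` is the low-level constructor from per-bin
#' probability mass, shared by direct, reweighted and WHAM projections:
#' ΔG_i = −kB·T·log(p_i / max p).
#'
#' @param mass per-bin probability mass (vector for 1D, matrix for 2D);
#'   nonnegative, zeros mark empty bins.
#' @param edges list of bin-edge vectors, one per axis.
#' @param temperature K.
#' @param counts optional raw occupancy counts with the same shape.
#' @param axes optional axis names.
#' @return Object of class `free_energy_profile` with fields `edges`,
#'   `centers`, `dG`, `mass`, `counts`, `reference` (index of the anchored
#'   bin), `temperature`, `axes`.
#' @export
profile_from_mass <- function(mass, edges, temperature, counts = NULL,
                              axes = NULL) {
  stopifnot(is.list(edges), length(edges) %in% c(1, 2), temperature > 0)
  m0 <- max(mass)
  if (!is.finite(m0) || m0 <= 0) stop("no occupied bins")
  dG <- -kB * temperature * log(mass / m0)
  dG[mass <= 0] <- Inf
  ref <- which(mass == m0)[1]
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  if (is.null(axes)) axes <- paste0("axis", seq_along(edges))
  structure(list(edges = edges, centers = centers, dG = dG,
                 mass = mass / sum(mass), counts = counts, reference = ref,
                 temperature = temperature, axes = axes),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  nb <- vapply(x$edges, function(e) length(e) - 1L, integer(1))
  occ <- sum(is.finite(x$dG))
  cat("<free_energy_profile> ", paste(nb, collapse = " x "), " bins over ",
      paste(x$axes, collapse = ", "), "; ", occ, " occupied; T = ",
      x$temperature, " K\n", sep = "")
  fin <- x$dG[is.finite(x$dG)]
  cat(sprintf("  dG range: 0 .. %.3f kcal/mol\n", max(fin)))
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  if (length(x$edges) == 1) {
    data.frame(bin_center = x$centers[[1]], dG = as.vector(x$dG),
               mass = as.vector(x$mass),
               empty = !is.finite(as.vector(x$dG)))
  } else {
    g <- expand.grid(x$centers[[1]], x$centers[[2]])
    names(g) <- x$axes
    g$dG <- as.vector(x$dG)
    g$mass <- as.vector(x$mass)
    g$empty <- !is.finite(g$dG)
    g
  }
}

.make_edges <- function(v, n_bins, range = NULL) {
  if (is.null(range)) range <- range(v)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)  # all-identical data
  seq(range[1], range[2], length.out = n_bins + 1)
}

# clamped variant: for looking up the bin of a sample known to be in range
.bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

# NA for out-of-range samples: histogram builders must drop, never clamp,
# or edge bins accumulate the whole out-of-range tail
.bin_index_drop <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

.auto_bins <- function(n) max(1L, as.integer(ceiling(sqrt(n))))

#' Direct Gibbs-energy projection from binned occupancies
#'
#' Bins samples along 1 or 2 coordinates and converts occupancies to Gibbs
#' energies via ΔG_i = −kB·T·log(k_i / k_0), where k_i is the occupation of
#' bin i and k_0 that of the most occupied bin. The automatic bin count is
#' ceiling(sqrt(N)) (per axis), always user-overridable.
#'
#' @param series a `cv_series`, or a numeric vector/matrix of samples.
#' @param axes column name(s) to project onto (1 or 2); defaults to the
#'   first column.
#' @param n_bins bin count, per axis (recycled for 2D), or `"auto"`.
#' @param temperature K; defaults to the series temperature.
#' @param weights optional per-sample probability weights (see
#'   [reweighted_projection()]).
#' @param range optional list of per-axis ranges.
#' @return a `free_energy_profile`.
#' @export
direct_projection <- function(series, axes = NULL, n_bins = "auto",
                              temperature = NULL, weights = NULL,
                              range = NULL) {
  if (inherits(series, "cv_series")) {
    if (is.null(temperature)) temperature <- series$temperature
    vals <- series$values
  } else {
    vals <- as.matrix(series)
    if (is.null(temperature)) temperature <- default_temperature
  }
  if (nrow(vals) == 0) stop("empty series")
  if (is.null(axes)) axes <- colnames(vals)[1]
  if (is.null(axes)) axes <- 1L
  stopifnot(length(axes) %in% c(1, 2))
  n <- nrow(vals)
  if (identical(n_bins, "auto")) n_bins <- .auto_bins(n)
  n_bins <- rep(as.integer(n_bins), length.out = length(axes))
  if (is.null(weights)) {
    w <- rep(1 / n, n)
  } else {
    stopifnot(length(weights) == n, all(weights >= 0))
    w <- weights / sum(weights)
  }
  if (!is.list(range) && !is.null(range)) range <- list(range)

  cols <- lapply(axes, function(a) {
    if (is.character(a) && !a %in% colnames(vals)) {
      stop(sprintf("axis '%s' not present in series", a))
    }
    vals[, a]
  })
  edges <- lapply(seq_along(cols), function(k) {
    .make_edges(cols[[k]], n_bins[k],
                if (!is.null(range)) range[[k]] else NULL)
  })
  idx <- lapply(seq_along(cols), function(k) {
    .bin_index_drop(cols[[k]], edges[[k]])
  })
  keep <- !Reduce(`|`, lapply(idx, is.na))
  if (!any(keep)) stop("no samples inside the requested range")

  if (length(axes) == 1) {
    i1 <- idx[[1]][keep]
    counts <- tabulate(i1, nbins = n_bins[1])
    mass <- as.vector(tapply(w[keep], factor(i1, levels = seq_len(n_bins[1])),
                             sum, default = 0))
  } else {
    i1 <- idx[[1]][keep]; i2 <- idx[[2]][keep]
    flat <- i1 + n_bins[1] * (i2 - 1L)
    counts <- matrix(tabulate(flat, nbins = n_bins[1] * n_bins[2]),
                     n_bins[1], n_bins[2])
    mass <- matrix(as.vector(tapply(
      w[keep], factor(flat, levels = seq_len(n_bins[1] * n_bins[2])),
      sum, default = 0)), n_bins[1], n_bins[2])
  }
  ax_names <- if (is.character(axes)) axes else paste0("axis", seq_along(axes))
  profile_from_mass(mass, edges, temperature, counts = counts,
                    axes = ax_names)
}

#' Reweighted Gibbs-energy projection
#'
#' Projects WHAM per-conformation weights onto arbitrary collective
#' variables: ΔG = −kB·T·log p with p the accumulated probability of the
#' conformations occupying each bin. With uniform weights this reduces
#' exactly to [direct_projection()].
#'
#' @param values numeric vector/matrix (or `cv_series`) of CV samples, one
#'   row per weighted conformation.
#' @param weights normalized per-conformation probabilities p_i.
#' @param axes,n_bins,temperature,range as in [direct_projection()].
#' @return a `free_energy_profile`.
#' @export
reweighted_projection <- function(values, weights, axes = NULL,
                                  n_bins = "auto",
                                  temperature = default_temperature,
                                  range = NULL) {
  direct_projection(values, axes = axes, n_bins = n_bins,
                    temperature = temperature, weights = weights,
                    range = range)
}

#' Discard the equilibration period of an umbrella window
#'
#' Removes frames with time < `t_eq` (default 2 ps, the usual equilibration
#' discard for short QM/MM umbrella windows).
#'
#' @param window an `umbrella_window`.
#' @param t_eq ps, >= 0.
#' @return the trimmed `umbrella_window`.
#' @export
equilibration_discard <- function(window, t_eq = 2) {
  stopifnot(inherits(window, "umbrella_window"), t_eq >= 0)
  if (t_eq == 0) return(window)
  keep <- window$series$times >= t_eq
  if (!any(keep)) {
    stop(sprintf("equilibration discard of %g ps leaves window at %g Å empty",
                 t_eq, window$center))
  }
  umbrella_window(cv_subset(window$series, keep), window$center,
                  window$force_constant)
}

# bias energies of every bin center under every window: nb x nw matrix
.bias_matrix <- function(centers_x, windows) {
  vapply(windows, function(w) {
    0.5 * w$force_constant * (centers_x - w$center)^2
  }, numeric(length(centers_x)))
}

#' Self-consistent WHAM over binned umbrella histograms
#'
#' Combines the biased histograms h_j(x) of a set of harmonic umbrella
#' windows into the unbiased density by iterating the coupled equations
#' \deqn{\rho(x) = \frac{\sum_j h_j(x)}
#'                      {\sum_j N_j e^{-\beta (U_j^{bias}(x) - F_j)}},\qquad
#'       F_j = -k_B T \log \sum_x \rho(x) e^{-\beta U_j^{bias}(x)}}
#' to self-consistency (max |ΔF_j| < `tolerance`), anchoring F of the first
#' window at 0. The PMF is −kB·T·log ρ anchored at its minimum.
#'
#' @param windows list of `umbrella_window` (force_constant 0 allowed:
#'   zero-bias windows reduce WHAM to the pooled histogram).
#' @param n_bins histogram bins over the biased coordinate (default 200).
#' @param tolerance kcal·mol⁻¹ on the window offsets F_j.
#' @param max_iter iteration cap.
#' @param temperature K; defaults to the first window's series temperature.
#' @param range optional histogram range (default: pooled sample range).
#' @return list with `solution` (class `wham_solution`: `F`, `iterations`,
#'   `converged`, `tolerance`, plus the histogram internals) and `profile`
#'   (a `free_energy_profile` over the biased coordinate).
#' @export
wham_solve <- function(windows, n_bins = 200, tolerance = 1e-6,
                       max_iter = 100000, temperature = NULL,
                       range = NULL) {
  stopifnot(length(windows) >= 1)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  if (is.null(temperature)) temperature <- windows[[1]]$series$temperature
  beta <- .beta(temperature)

  xs <- lapply(windows, function(w) w$series$values[, 1])
  edges <- .make_edges(unlist(xs), n_bins, range)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(windows)
  counts <- vapply(xs, function(v) {
    i <- .bin_index_drop(v, edges)
    tabulate(i[!is.na(i)], nbins = n_bins)
  }, numeric(n_bins))
  counts <- matrix(counts, nrow = n_bins, ncol = nw)
  N <- colSums(counts)
  numer <- rowSums(counts)

  # warn when consecutive windows share no occupied bins
  disconnected <- FALSE
  if (nw > 1) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    for (k in seq_len(nw - 1)) {
      if (!any(counts[, ord[k]] > 0 & counts[, ord[k + 1]] > 0)) {
        disconnected <- TRUE
      }
    }
    if (disconnected) {
      warning("empty inter-window histogram overlap: PMF support disconnected")
    }
  }

  U <- .bias_matrix(centers, windows)          # nb x nw
  expU <- exp(-beta * U)
  f <- numeric(nw)                              # F_j
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    denom <- expU %*% (N * exp(beta * f))       # nb x 1
    rho <- numer / pmax(as.vector(denom), .Machine$double.xmin)
    fn <- -log(pmax(as.vector(t(expU) %*% rho), .Machine$double.xmin)) /
      beta
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tolerance) { converged <- TRUE; break }
  }
  denom <- expU %*% (N * exp(beta * f))
  rho <- numer / pmax(as.vector(denom), .Machine$double.xmin)
  rho[numer == 0] <- 0
  mass <- rho / sum(rho)

  solution <- structure(
    list(F = f, iterations = it, converged = converged,
         tolerance = tolerance, temperature = temperature,
         edges = edges, centers = centers, mass = mass, counts = counts,
         N = N, disconnected = disconnected,
         window_centers = vapply(windows, `[[`, numeric(1), "center"),
         window_k = vapply(windows, `[[`, numeric(1), "force_constant")),
    class = "wham_solution")
  profile <- profile_from_mass(mass, list(edges), temperature,
                               counts = numer, axes = "x")
  list(solution = solution, profile = profile)
}

#' @export
print.wham_solution <- function(x, ...) {
  cat("<wham_solution> ", length(x$F), " windows, ", length(x$centers),
      " bins; ", x$iterations, " iterations; converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' Per-conformation WHAM weights
#'
#' The individual probability of each retained conformation,
#' \deqn{p_i \propto \Big(\sum_j N_j e^{\beta (F_j - U_j^{bias}(x_i))}\Big)^{-1},}
#' normalized globally so that Σ p_i = 1 over all samples of all windows.
#' Bias energies are evaluated at the actual sample positions (not bin
#' centers), which is what makes the weights usable for projections onto
#' any auxiliary CV carried alongside the biased coordinate.
#'
#' @param windows the window list the solution was computed from.
#' @param solution a converged `wham_solution`.
#' @param at `"sample"` (default) evaluates U_j at each sample's actual
#'   position; `"bin_center"` uses the sample's histogram-bin center, which
#'   makes the accumulated weights per bin algebraically identical to the
#'   solution's binned density.
#' @return list with `weights` (normalized p_i over all samples, in window
#'   order), `window` (integer window index per sample) and `x` (biased
#'   coordinate per sample).
#' @export
conformation_weights <- function(windows, solution,
                                 at = c("sample", "bin_center")) {
  at <- match.arg(at)
  stopifnot(inherits(solution, "wham_solution"))
  if (!solution$converged) {
    stop("conformation_weights requires a converged WHAM solution")
  }
  if (length(windows) != length(solution$F) ||
      any(abs(vapply(windows, `[[`, numeric(1), "center") -
              solution$window_centers) > 1e-12)) {
    stop("windows do not match the WHAM solution they are paired with")
  }
  beta <- .beta(solution$temperature)
  xs <- lapply(windows, function(w) w$series$values[, 1])
  x <- unlist(xs)
  win <- rep(seq_along(windows), vapply(xs, length, integer(1)))
  xeval <- if (at == "bin_center") {
    solution$centers[.bin_index(x, solution$edges)]
  } else {
    x
  }
  U <- .bias_matrix(xeval, windows)            # nsamples x nw
  p <- 1 / as.vector(exp(beta * sweep(-U, 2, solution$F, "+")) %*%
                       solution$N)
  p <- p / sum(p)
  list(weights = p, window = win, x = x)
}

#' Time-block convergence diagnostic for umbrella PMFs
#'
#' Recomputes the WHAM PMF on cumulative time blocks of every window (the
#' first 1/n, 2/n, ... of each window for `scheme = "direct"`; the same
#' fractions taken from the end of the series for `scheme = "reverse"`) and
#' reports the maximum absolute ΔG difference between successive cumulative
#' PMFs over bins occupied in both. Sampling is declared converged when the
#' final deviation falls below `tolerance` (default 1 kcal·mol⁻¹).
#'
#' @param windows list of `umbrella_window`.
#' @param scheme `"direct"` or `"reverse"`.
#' @param n_blocks number of cumulative blocks, >= 2.
#' @param tolerance kcal·mol⁻¹.
#' @param n_bins,range passed to [wham_solve()]; the histogram range is
#'   fixed from the full data so successive PMFs share bins.
#' @return list with `profiles` (per block), `deviations` (length
#'   n_blocks - 1), `converged`.
#' @export
convergence_check <- function(windows, scheme = c("direct", "reverse"),
                              n_blocks = 4, tolerance = 1,
                              n_bins = 200, range = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_blocks >= 2)
  if (is.null(range)) {
    range <- range(unlist(lapply(windows, function(w) w$series$values[, 1])))
  }
  take <- function(w, frac) {
    n <- n_frames(w$series)
    k <- max(1L, floor(frac * n))
    idx <- if (scheme == "direct") seq_len(k) else seq(n - k + 1L, n)
    umbrella_window(cv_subset(w$series, idx), w$center, w$force_constant)
  }
  profiles <- lapply(seq_len(n_blocks), function(b) {
    ws <- lapply(windows, take, frac = b / n_blocks)
    wham_solve(ws, n_bins = n_bins, range = range)$profile
  })
  deviations <- vapply(seq_len(n_blocks - 1), function(b) {
    g1 <- profiles[[b]]$dG; g2 <- profiles[[b + 1]]$dG
    ok <- is.finite(g1) & is.finite(g2)
    if (!any(ok)) stop("no commonly occupied bins between successive blocks")
    max(abs(g1[ok] - g2[ok]))
  }, numeric(1))
  list(profiles = profiles, deviations = deviations,
       converged = deviations[n_blocks - 1] < tolerance,
       scheme = scheme, tolerance = tolerance)
}

#' Eyring transition-state-theory conversion between barrier and rate
#'
#' k = (kB·T/h)·exp(−ΔG‡ / (kB·T)), and its inverse. The prefactor kB·T/h
#' is about 6.46e12 s⁻¹ at 310 K.
#'
#' @param value barrier (kcal·mol⁻¹) or rate (s⁻¹), per `direction`.
#' @param direction `"barrier_to_rate"` or `"rate_to_barrier"`.
#' @param temperature K, > 0.
#' @return rate in s⁻¹ or barrier in kcal·mol⁻¹.
#' @export
tst_convert <- function(value,
                        direction = c("barrier_to_rate", "rate_to_barrier"),
                        temperature = default_temperature) {
  direction <- match.arg(direction)
  stopifnot(temperature > 0)
  pref <- kB * temperature / planck_h
  if (direction == "barrier_to_rate") {
    value * 0 + pref * exp(-value / (kB * temperature))
  } else {
    if (any(value <= 0)) stop("rate must be positive")
    -kB * temperature * log(value / pref)
  }
}
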