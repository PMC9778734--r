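#' Harmonic bias specification
#'
#' Describes the restraint applied to the sampled coordinate: `none`,
#' a `fixed_harmonic` umbrella \eqn{k/2 (x - c)^2}, or a `moving_harmonic`
#' whose center is pulled linearly from `center_start` to `center_end` over
#' `duration` ps (a steered-dynamics surrogate used to seed umbrella
#' windows).
#'
#' @param kind one of `"none"`, `"fixed_harmonic"`, `"moving_harmonic"`.
#' @param center Å (fixed_harmonic).
#' @param force_constant kcal·mol⁻¹·Å⁻², >= 0.
#' @param center_start,center_end,duration moving_harmonic schedule
#'   (Å, Å, ps); the schedule is monotone by construction.
#' @return Object of class `bias_spec`.
#' @export
bias_spec <- function(kind = c("none", "fixed_harmonic", "moving_harmonic"),
                      center = NULL, force_constant = 0,
                      center_start = NULL, center_end = NULL,
                      duration = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(force_constant), force_constant >= 0)
  if (kind == "fixed_harmonic") stopifnot(is.numeric(center))
  if (kind == "moving_harmonic") {
    stopifnot(is.numeric(center_start), is.numeric(center_end),
              is.numeric(duration), duration > 0)
  }
  structure(list(kind = kind, center = center,
                 force_constant = force_constant,
                 center_start = center_start, center_end = center_end,
                 duration = duration),
            class = "bias_spec")
}

.bias_center <- function(bias, t) {
  switch(bias$kind,
    none = NA_real_,
    fixed_harmonic = bias$center,
    moving_harmonic = bias$center_start +
      (bias$center_end - bias$center_start) * pmin(t / bias$duration, 1))
}

#' Bias potential energy at positions x, time t
#' @param bias a `bias_spec`.
#' @param x positions, Å.
#' @param t time, ps (only used by moving_harmonic).
#' @export
bias_energy <- function(bias, x, t = 0) {
  if (bias$kind == "none" || bias$force_constant == 0) return(rep(0, length(x)))
  c0 <- .bias_center(bias, t)
  0.5 * bias$force_constant * (x - c0)^2
}

#' Overdamped Langevin sampling on an analytic potential
#'
#' First-order Euler–Maruyama integration of Brownian dynamics,
#' \deqn{x \leftarrow x - \frac{dt}{\gamma} U'(x) +
#'       \sqrt{2 k_B T \, dt / \gamma}\; \mathcal{N}(0,1),}
#' which samples the Boltzmann distribution of `potential` (+ bias) exactly
#' in the long-time, small-step limit. Reflecting walls are applied at the
#' potential-domain edges so tabulated surfaces cannot be escaped. The
#' generator is a pure function of `seed`.
#'
#' @param potential a 1D `potential_spec`.
#' @param bias a `bias_spec` (default: none).
#' @param n_steps number of retained samples.
#' @param dt time step, ps; `NULL` (default) picks
#'   `0.05 * friction / (kappa_max + k_bias)` from the maximum curvature of
#'   the potential plus the bias stiffness, keeping `dt * kappa / friction`
#'   a factor 2 below the 0.1 stability/accuracy ceiling while minimizing
#'   the correlation time in samples.
#' @param temperature K (0 allowed: deterministic steepest-descent drift).
#' @param friction γ, ps⁻¹.
#' @param x0 starting position, Å, inside the domain.
#' @param seed integer RNG seed.
#' @return A `cv_series` with one coordinate `"x"`; sampling times are
#'   `dt * (1:n_steps)`.
#' @examples
#' pot <- potential_spec("harmonic", list(kappa = 10, center = 0))
#' s <- simulate_langevin(pot, n_steps = 1000, seed = 1)
#' var(cv_column(s, "x"))  # ~ kB*310/10
#' @export
simulate_langevin <- function(potential, bias = bias_spec("none"),
                              n_steps, dt = NULL,
                              temperature = default_temperature,
                              friction = 1, x0 = NULL, seed = 1) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(bias, "bias_spec"),
            friction > 0, n_steps >= 1, temperature >= 0)
  if (is.null(dt)) {
    dt <- 0.05 * friction /
      (potential_stiffness(potential) + bias$force_constant)
  }
  stopifnot(dt > 0)
  dom <- potential$domain
  if (is.null(x0)) x0 <- mean(dom)
  if (x0 < dom[1] || x0 > dom[2]) stop("x0 outside potential domain")

  set.seed(as.integer(seed %% .Machine$integer.max))
  mob <- dt / friction
  sigma <- sqrt(2 * kB * temperature * dt / friction)
  noise <- if (temperature > 0) stats::rnorm(n_steps) else numeric(n_steps)

  kb_bias <- bias$force_constant
  moving <- bias$kind == "moving_harmonic" && kb_bias > 0
  fixed <- bias$kind == "fixed_harmonic" && kb_bias > 0
  cfix <- if (fixed) bias$center else 0

  # hoist the force law out of the hot loop (avoids S3 dispatch per step)
  p <- potential$parameters
  force_fn <- switch(potential$form,
    harmonic = {
      kap <- p$kappa; ctr <- p$center
      function(x) -kap * (x - ctr)
    },
    double_well = {
      a <- 4 * p$barrier / p$half_separation^2; b2 <- p$half_separation^2
      function(x) -a * x * (x * x / b2 - 1)
    },
    tabulated_1d = function(x) potential_force(potential, x),
    separable_2d = stop("simulate_langevin is one-dimensional"))

  x <- x0
  lo <- dom[1]; hi <- dom[2]
  out <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    f <- force_fn(x)
    if (fixed) {
      f <- f - kb_bias * (x - cfix)
    } else if (moving) {
      f <- f - kb_bias * (x - .bias_center(bias, (i - 1) * dt))
    }
    x <- x + mob * f + sigma * noise[i]
    # reflecting walls
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
    if (x < lo || x > hi) x <- 0.5 * (lo + hi)  # pathological big step
    out[i] <- x
  }
  if (any(!is.finite(out))) stop("Langevin integration diverged")
  cv_series(dt * seq_len(n_steps), out,
            temperature = max(temperature, 1e-12), labels = "x")
}

#' Umbrella window: biased samples plus their restraint
#'
#' @param series `cv_series` of the biased coordinate (first column) plus
#'   optional auxiliary CV columns carried along for reweighted projections.
#' @param center Å; restraint center.
#' @param force_constant kcal·mol⁻¹·Å⁻², >= 0 (0 means unbiased).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(series, center, force_constant) {
  stopifnot(inherits(series, "cv_series"), is.numeric(center),
            is.numeric(force_constant), force_constant >= 0,
            n_frames(series) >= 1)
  structure(list(series = series, center = center,
                 force_constant = force_constant),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat("<umbrella_window> center ", x$center, " Å, k = ", x$force_constant,
      " kcal/mol/Å², ", n_frames(x$series), " frames\n", sep = "")
  invisible(x)
}

#' Generate a ladder of umbrella windows on an analytic potential
#'
#' One fixed-harmonic window per center, sampled by [simulate_langevin()]
#' under `potential` plus the bias, started at the window center. Per-window
#' seeds are derived deterministically from `seed`. Defaults follow common
#' QM/MM umbrella protocols: 0.10 Å spacing and a force constant in the
#' 100–200 kcal·mol⁻¹·Å⁻² range (150 when unspecified). A warning is issued
#' if spacing exceeds `2*sqrt(kB*T/k)`, i.e. when neighboring windows no
#' longer overlap.
#'
#' @param potential a 1D `potential_spec`.
#' @param centers sorted window centers, Å. Default: the potential domain
#'   tiled every 0.10 Å.
#' @param force_constant kcal·mol⁻¹·Å⁻² (default 150).
#' @param steps_per_window samples per window.
#' @param temperature K.
#' @param dt,friction integrator parameters (see [simulate_langevin()]).
#' @param seed master integer seed.
#' @return list of `umbrella_window`.
#' @export
generate_umbrella_set <- function(potential, centers = NULL,
                                  force_constant = 150,
                                  steps_per_window = 10000,
                                  temperature = default_temperature,
                                  dt = NULL, friction = 1, seed = 1) {
  stopifnot(inherits(potential, "potential_spec"))
  if (force_constant <= 0) stop("force_constant must be > 0")
  if (is.null(centers)) {
    centers <- seq(potential$domain[1], potential$domain[2], by = 0.10)
  }
  if (length(centers) == 0) stop("centers must be nonempty")
  if (is.unsorted(centers)) stop("centers must be sorted")
  if (length(centers) > 1) {
    sp <- max(diff(centers))
    if (sp > 2 * sqrt(kB * temperature / force_constant)) {
      warning(sprintf(
        "window spacing %.3g Å exceeds 2*sqrt(kBT/k) = %.3g Å; histograms may not overlap",
        sp, 2 * sqrt(kB * temperature / force_constant)))
    }
  }
  lapply(seq_along(centers), function(j) {
    c_j <- centers[j]
    x0 <- min(max(c_j, potential$domain[1]), potential$domain[2])
    s <- simulate_langevin(
      potential,
      bias_spec("fixed_harmonic", center = c_j,
                force_constant = force_constant),
      n_steps = steps_per_window, dt = dt, temperature = temperature,
      friction = friction, x0 = x0,
      seed = (seed + 7919 * j) %% .Machine$integer.max)
    umbrella_window(s, c_j, force_constant)
  })
}
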