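#' Analytic one-dimensional potentials with known free-energy profiles
#'
#' A `potential_spec` describes the energy surface on which synthetic biased
#' trajectories are generated. Two closed-form families are provided —
#' `harmonic`, \eqn{U(x) = \kappa/2 (x - x_0)^2}, and `double_well`,
#' \eqn{U(x) = \Delta U^\ddagger ((x/b)^2 - 1)^2} with minima at \eqn{\pm b},
#' \eqn{U(\pm b) = 0} and barrier \eqn{U(0) = \Delta U^\ddagger} — plus a
#' `tabulated_1d` form interpolated from (x, U) nodes and a `separable_2d`
#' form built from two independent 1D specs. The exact potential doubles as
#' the exact potential of mean force, which is what makes the generator a
#' useful ground truth for WHAM and projection machinery.
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"tabulated_1d"`,
#'   `"separable_2d"`.
#' @param parameters named list: harmonic needs `kappa`
#'   (kcal·mol⁻¹·Å⁻²) and `center` (Å); double_well needs `barrier`
#'   (kcal·mol⁻¹, \eqn{\Delta U^\ddagger}) and `half_separation` (Å, b);
#'   tabulated_1d needs `x` and `u` node vectors; separable_2d needs `x_spec`
#'   and `y_spec`, themselves `potential_spec` objects.
#' @param domain closed interval (length-2 numeric, Å) on which the potential
#'   is defined; reflecting walls are applied there during sampling. For
#'   separable_2d it is taken from the component specs.
#'
#' @return An object of class `potential_spec`.
#' @examples
#' dw <- potential_spec("double_well",
#'                      list(barrier = 5, half_separation = 1),
#'                      domain = c(-1.6, 1.6))
#' potential_energy(dw, c(-1, 0, 1))   # 0, 5, 0
#' @export
potential_spec <- function(form = c("harmonic", "double_well",
                                    "tabulated_1d", "separable_2d"),
                           parameters = list(), domain = NULL) {
  form <- match.arg(form)
  p <- parameters
  if (form == "harmonic") {
    stopifnot(is.numeric(p$kappa), p$kappa > 0, is.numeric(p$center))
    if (is.null(domain)) {
      domain <- p$center + c(-1, 1) * 10 * sqrt(1 / p$kappa + 1)
    }
  } else if (form == "double_well") {
    stopifnot(is.numeric(p$barrier), p$barrier > 0,
              is.numeric(p$half_separation), p$half_separation > 0)
    if (is.null(domain)) domain <- c(-1.6, 1.6) * p$half_separation
  } else if (form == "tabulated_1d") {
    stopifnot(is.numeric(p$x), is.numeric(p$u), length(p$x) == length(p$u),
              length(p$x) >= 2, !is.unsorted(p$x))
    if (any(!is.finite(p$u))) {
      stop("tabulated potential has non-finite values (holes) on its domain")
    }
    if (is.null(domain)) domain <- range(p$x)
  } else if (form == "separable_2d") {
    stopifnot(inherits(p$x_spec, "potential_spec"),
              inherits(p$y_spec, "potential_spec"))
    domain <- list(p$x_spec$domain, p$y_spec$domain)
  }
  if (form != "separable_2d") {
    stopifnot(length(domain) == 2, domain[1] < domain[2],
              all(is.finite(domain)))
  }
  structure(list(form = form, parameters = p, domain = domain),
            class = "potential_spec")
}

#' @rdname potential_spec
#' @param spec a `potential_spec`.
#' @param x positions (Å); for separable_2d a two-column matrix.
#' @export
potential_energy <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  p <- spec$parameters
  switch(spec$form,
    harmonic = 0.5 * p$kappa * (x - p$center)^2,
    double_well = p$barrier * ((x / p$half_separation)^2 - 1)^2,
    tabulated_1d = stats::approx(p$x, p$u, xout = x, rule = 2)$y,
    separable_2d = potential_energy(p$x_spec, x[, 1]) +
                   potential_energy(p$y_spec, x[, 2]))
}

#' @rdname potential_spec
#' @export
potential_force <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  p <- spec$parameters
  f <- switch(spec$form,
    harmonic = -p$kappa * (x - p$center),
    double_well = -4 * p$barrier / p$half_separation^2 *
      x * ((x / p$half_separation)^2 - 1),
    tabulated_1d = {
      h <- 1e-5 * diff(spec$domain)
      xm <- pmax(x - h, spec$domain[1]); xp <- pmin(x + h, spec$domain[2])
      -(potential_energy(spec, xp) - potential_energy(spec, xm)) / (xp - xm)
    },
    separable_2d = stop("use component specs for 2D forces"))
  if (any(!is.finite(f))) stop("non-finite force encountered")
  f
}

#' Maximum curvature (stiffness) of a 1D potential over its domain
#'
#' Used to pick a stable integration step: the overdamped integrator
#' requires dt * kappa_max / friction well below 1.
#'
#' @param spec a 1D `potential_spec`.
#' @return kcal·mol⁻¹·Å⁻².
#' @export
potential_stiffness <- function(spec) {
  stopifnot(inherits(spec, "potential_spec"))
  p <- spec$parameters
  switch(spec$form,
    harmonic = p$kappa,
    double_well = {
      # U'' = (4 dU / b^2) (3 x^2 / b^2 - 1), maximal at the domain edge
      xm <- max(abs(spec$domain))
      4 * p$barrier / p$half_separation^2 *
        max(1, 3 * xm^2 / p$half_separation^2 - 1)
    },
    tabulated_1d = {
      xs <- seq(spec$domain[1], spec$domain[2], length.out = 512)
      u <- potential_energy(spec, xs)
      h <- diff(xs)[1]
      max(abs(diff(u, differences = 2)) / h^2, 1e-8)
    },
    separable_2d = stop("stiffness of 2D specs: use the component specs"))
}

#' Numerically integrated Boltzmann free-energy profile of a potential
#'
#' Integrates \eqn{\exp(-\beta U)} over each bin of a grid and returns
#' \eqn{-k_B T \log} of the bin mass, anchored so the minimum is zero. This
#' is the exact (up to quadrature) PMF that umbrella sampling plus WHAM
#' should recover on these analytic surfaces.
#'
#' @param spec a 1D `potential_spec`.
#' @param edges bin edges (Å), increasing.
#' @param temperature K.
#' @param n_quad quadrature points per bin.
#' @return `free_energy_profile` over the given bins.
#' @export
boltzmann_profile <- function(spec, edges, temperature = default_temperature,
                              n_quad = 64) {
  stopifnot(length(edges) >= 2, !is.unsorted(edges))
  beta <- .beta(temperature)
  nb <- length(edges) - 1
  mass <- vapply(seq_len(nb), function(i) {
    xs <- seq(edges[i], edges[i + 1], length.out = n_quad)
    u <- potential_energy(spec, xs)
    # trapezoid on exp(-beta * (u - umin)) to avoid underflow
    u0 <- min(u)
    exp(-beta * u0) * sum(diff(xs) * (exp(-beta * (u - u0))[-1] +
                                      exp(-beta * (u - u0))[-n_quad]) / 2)
  }, numeric(1))
  profile_from_mass(mass / sum(mass), list(edges), temperature)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$form, "\n")
  if (x$form != "separable_2d") {
    cat("  domain: [", x$domain[1], ",", x$domain[2], "] Å\n")
  }
  str(x$parameters, give.attr = FALSE, indent.str = "  ")
  invisible(x)
}
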