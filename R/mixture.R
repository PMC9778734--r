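#' Correlated active-site distance series from a Gaussian-mixture model
#'
#' Emulates the multi-basin structure of enzyme active-site distance data:
#' frames are drawn from a mixture of multivariate normal basins over named
#' distance coordinates (e.g. `d_acid`, `d_nuc`, `d_glyc`, `d_Glu233_WAT`,
#' `d_glyc_WAT`). Negative draws are rejected and resampled — distances are
#' physically nonnegative; the induced truncation bias is negligible as long
#' as basin means are several standard deviations above zero.
#'
#' @param basins list of basins, each `list(mean = named numeric vector,
#'   cov = covariance matrix (or a scalar/vector for a diagonal), weight)`.
#'   All basins must share coordinate names; weights must be positive and
#'   sum to 1.
#' @param n_frames number of frames, > 0.
#' @param seed integer seed (the generator is a pure function of it).
#' @param dt frame spacing, ps.
#' @param temperature K, stored on the result.
#' @return a `cv_series` with one column per coordinate and an attribute
#'   `basin` (integer basin index per frame).
#' @examples
#' b <- list(
#'   list(mean = c(d_acid = 4.6, d_nuc = 5.1), cov = 0.04, weight = 0.8),
#'   list(mean = c(d_acid = 7.5, d_nuc = 8.0), cov = 0.04, weight = 0.2))
#' s <- generate_active_site_series(b, n_frames = 100, seed = 1)
#' @export
generate_active_site_series <- function(basins, n_frames, seed = 1,
                                        dt = 1,
                                        temperature = default_temperature) {
  if (n_frames <= 0) stop("n_frames must be positive")
  stopifnot(length(basins) >= 1)
  labels <- names(basins[[1]]$mean)
  if (is.null(labels)) stop("basin means must be named distance vectors")
  d <- length(labels)
  w <- vapply(basins, function(b) b$weight, numeric(1))
  if (any(w <= 0)) stop("basin weights must be positive")
  if (abs(sum(w) - 1) > 1e-8) stop("basin weights must sum to 1")

  chols <- lapply(basins, function(b) {
    mu <- b$mean[labels]
    if (any(is.na(mu))) stop("basins disagree on coordinate names")
    if (any(mu < 0)) stop("distance means must be nonnegative")
    cv <- b$cov
    if (is.null(dim(cv))) cv <- diag(rep(cv, length.out = d), nrow = d)
    if (!isTRUE(all.equal(cv, t(cv)))) stop("covariance must be symmetric")
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-12)) stop("degenerate (non-PSD) covariance")
    # allow exactly-zero covariance (deterministic basin)
    if (all(abs(cv) < 1e-300)) return(matrix(0, d, d))
    chol(cv + diag(1e-12, d))
  })

  set.seed(as.integer(seed %% .Machine$integer.max))
  which_basin <- sample.int(length(basins), n_frames, replace = TRUE, prob = w)
  vals <- matrix(NA_real_, n_frames, d, dimnames = list(NULL, labels))
  for (i in seq_len(n_frames)) {
    k <- which_basin[i]
    mu <- basins[[k]]$mean[labels]
    repeat {
      x <- mu + drop(stats::rnorm(d) %*% chols[[k]])
      if (all(x >= 0)) break
    }
    vals[i, ] <- x
  }
  out <- cv_series(dt * seq_len(n_frames), vals, temperature = temperature)
  attr(out, "basin") <- which_basin
  out
}
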