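#' Collective-variable time series
#'
#' The universal currency between pipeline stages: a strictly increasing time
#' axis (ps), one column per named coordinate (Å or composite-CV units), and
#' the temperature (K) at which the samples were drawn.
#'
#' @param times numeric vector, ps, strictly increasing.
#' @param values numeric vector or matrix, one row per frame.
#' @param temperature K, > 0.
#' @param labels coordinate names; defaults to column names of `values` or
#'   `"cv1"`, `"cv2"`, ...
#' @return An object of class `cv_series`: list with `times`, `values`
#'   (matrix with column names), `temperature`.
#' @export
cv_series <- function(times, values, temperature = default_temperature,
                      labels = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("cv", seq_len(ncol(values)))
  }
  stopifnot(length(labels) == ncol(values),
            length(times) == nrow(values),
            is.numeric(temperature), temperature > 0)
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("cv_series must not contain non-finite values")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  colnames(values) <- labels
  structure(list(times = as.numeric(times), values = values,
                 temperature = temperature),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat("<cv_series> ", nrow(x$values), " frames x ", ncol(x$values),
      " coordinate(s): ", paste(colnames(x$values), collapse = ", "),
      "\n  time: ", x$times[1], " .. ", x$times[length(x$times)],
      " ps; temperature: ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cv_series <- function(x, ...) {
  data.frame(time_ps = x$times, x$values, check.names = FALSE)
}

#' Number of frames in a cv_series
#' @param series a `cv_series`.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "cv_series"))
  nrow(series$values)
}

#' Subset a cv_series by frame index
#' @param series a `cv_series`.
#' @param idx integer or logical frame index.
#' @export
cv_subset <- function(series, idx) {
  stopifnot(inherits(series, "cv_series"))
  v <- series$values[idx, , drop = FALSE]
  if (nrow(v) == 0) stop("subset leaves an empty cv_series")
  cv_series(series$times[idx], v, series$temperature)
}

#' Extract one named coordinate as a numeric vector
#' @param series a `cv_series`.
#' @param label coordinate name.
#' @export
cv_column <- function(series, label) {
  stopifnot(inherits(series, "cv_series"))
  if (!label %in% colnames(series$values)) {
    stop(sprintf("coordinate '%s' not present (have: %s)", label,
                 paste(colnames(series$values), collapse = ", ")))
  }
  series$values[, label]
}
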