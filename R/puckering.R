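#' Six-membered-ring geometry
#'
#' Positions of the six ring atoms of one frame, in the fixed ring-atom
#' convention used throughout the package: the ring oxygen (O5) first, then
#' C1..C5 in IUPAC numbering order. This convention fixes the origin of the
#' puckering phase angle so that the alpha-D-glucopyranose chair with C4
#' above and C1 below the mean plane classifies as `4C1` (theta = 0).
#'
#' @param positions 6 x 3 numeric matrix, Å, rows ordered O5, C1..C5.
#' @param frame optional frame identifier.
#' @return Object of class `ring_geometry`.
#' @export
ring_geometry <- function(positions, frame = NA) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || nrow(positions) != 6 || ncol(positions) != 3) {
    stop("ring_geometry requires a 6 x 3 numeric position matrix")
  }
  if (any(!is.finite(positions))) stop("non-finite ring coordinates")
  structure(list(positions = positions, frame = frame),
            class = "ring_geometry")
}

# in-plane phase of ring atom j (1-based), and the puckering-mode phase
.ring_A1 <- 2 * pi * (0:5) / 6
.ring_A2 <- 4 * pi * (0:5) / 6
.ring_parity <- rep(c(1, -1), 3)

#' Cremer–Pople puckering coordinates of a six-membered ring
#'
#' Implements the classical construction: translate to the geometric
#' center, form the mean-plane normal from the two trigonometrically
#' weighted lattice sums
#' \eqn{R' = \sum_j r_j \sin(2\pi j/6)}, \eqn{R'' = \sum_j r_j \cos(2\pi j/6)},
#' take out-of-plane displacements \eqn{z_j = r_j \cdot \hat n}, and project
#' \deqn{q_2 \cos\phi_2 = \sqrt{1/3} \sum_j z_j \cos(4\pi j/6), \quad
#'       q_2 \sin\phi_2 = -\sqrt{1/3} \sum_j z_j \sin(4\pi j/6), \quad
#'       q_3 = \sqrt{1/6} \sum_j (-1)^j z_j,}
#' with total amplitude \eqn{Q = \sqrt{q_2^2 + q_3^2}} and polar angle
#' \eqn{\theta = \arccos(q_3 / Q)}. By construction \eqn{\sum_j z_j = 0}.
#'
#' @param ring a `ring_geometry` (or a bare 6 x 3 matrix).
#' @param planarity_tol rings with Q below this (Å) are flagged planar and
#'   get undefined phi/theta plus the `"planar"` label sentinel.
#' @return Object of class `pucker_state`: `Q` (Å), `phi` (deg, [0, 360)),
#'   `theta` (deg, [0, 180]), `planar` flag, `conformer` label, and the
#'   internal amplitudes `q2`, `q3` and displacements `z`.
#' @export
cremer_pople <- function(ring, planarity_tol = 0.01) {
  if (!inherits(ring, "ring_geometry")) ring <- ring_geometry(ring)
  r <- sweep(ring$positions, 2, colMeans(ring$positions))
  rp <- colSums(r * sin(.ring_A1))
  rpp <- colSums(r * cos(.ring_A1))
  n <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
         rp[3] * rpp[1] - rp[1] * rpp[3],
         rp[1] * rpp[2] - rp[2] * rpp[1])
  nn <- sqrt(sum(n^2))
  scale <- mean(sqrt(rowSums(r^2)))
  if (!is.finite(nn) || nn < 1e-9 * max(scale^2, 1e-12)) {
    stop("degenerate ring geometry: atoms coincident or collinear")
  }
  z <- drop(r %*% (n / nn))
  q2c <- sqrt(1 / 3) * sum(z * cos(.ring_A2))
  q2s <- -sqrt(1 / 3) * sum(z * sin(.ring_A2))
  q3 <- sqrt(1 / 6) * sum(z * .ring_parity)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  planar <- Q < planarity_tol
  if (planar) {
    phi <- NA_real_; theta <- NA_real_
  } else {
    phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
    theta <- acos(max(-1, min(1, q3 / Q))) * 180 / pi
  }
  st <- structure(list(Q = Q, phi = phi, theta = theta, q2 = q2, q3 = q3,
                       planar = planar, z = z, frame = ring$frame,
                       conformer = NA_character_),
                  class = "pucker_state")
  st$conformer <- classify_conformer(st)
  st
}

#' @export
print.pucker_state <- function(x, ...) {
  if (x$planar) {
    cat(sprintf("<pucker_state> planar (Q = %.4f Å)\n", x$Q))
  } else {
    cat(sprintf("<pucker_state> %s  Q = %.3f Å, phi = %.1f°, theta = %.1f°\n",
                x$conformer, x$Q, x$phi, x$theta))
  }
  invisible(x)
}

# ---- canonical conformer table ---------------------------------------------

# Ideal out-of-plane displacement pattern for each named conformer, in ring
# order O5(1), C1..C5(2..6). Superscript atoms sit above the plane (+),
# subscript atoms below (-). The (phi, theta) vertex is obtained by
# projecting the pattern onto the two puckering modes — never hand-typed.
.conformer_patterns <- function() {
  at <- c("O" = 1, "1" = 2, "2" = 3, "3" = 4, "4" = 5, "5" = 6)
  pat <- list()
  z <- function(up = character(), down = character(), base = rep(0, 6)) {
    v <- base
    v[at[up]] <- v[at[up]] + 1
    v[at[down]] <- v[at[down]] - 1
    v
  }
  # chairs: all six atoms alternate; named by the C1/C4 exo pair
  pat[["4C1"]] <- .ring_parity          # O5, C2, C4 up; C1, C3, C5 down
  pat[["1C4"]] <- -.ring_parity
  # boats: para pair displaced to one side, the other four to the other
  boat <- function(a, b) { v <- rep(-1, 6); v[at[c(a, b)]] <- 2; v }
  pat[["14B"]] <- boat("1", "4"); pat[["B14"]] <- -boat("1", "4")
  pat[["25B"]] <- boat("2", "5"); pat[["B25"]] <- -boat("2", "5")
  pat[["3OB"]] <- boat("3", "O"); pat[["B3O"]] <- -boat("3", "O")
  # skews (twist-boats): one para pair in plane, the others up/down
  pat[["3S1"]] <- z(up = c("3", "O"), down = c("1", "4"))
  pat[["1S3"]] <- -pat[["3S1"]]
  pat[["5S1"]] <- z(up = c("5", "2"), down = c("1", "4"))
  pat[["1S5"]] <- -pat[["5S1"]]
  pat[["OS2"]] <- z(up = c("O", "3"), down = c("2", "5"))
  pat[["2SO"]] <- -pat[["OS2"]]
  # half-chairs: adjacent pair on opposite sides, four atoms coplanar
  hc <- list(c("O", "1"), c("1", "2"), c("2", "3"),
             c("3", "4"), c("4", "5"), c("5", "O"))
  for (e in hc) {
    pat[[paste0(e[1], "H", e[2])]] <- z(up = e[1], down = e[2])
    pat[[paste0(e[2], "H", e[1])]] <- z(up = e[2], down = e[1])
  }
  # envelopes: single flap atom
  for (a in names(at)) {
    pat[[paste0(a, "E")]] <- z(up = a)
    pat[[paste0("E", a)]] <- z(down = a)
  }
  pat
}

.pucker_env <- new.env(parent = emptyenv())

#' Canonical conformer table
#'
#' The 38 canonical six-ring pucker vertices (2 chairs, 6 boats, 6 skews,
#' 12 half-chairs, 12 envelopes) as rows of (label, phi, theta), generated
#' programmatically from ideal displacement patterns (see
#' [generate_ring_conformer()]). Chairs sit at theta 0/180, boats and skews
#' on the equator, half-chairs near 50.8/129.2 and envelopes near
#' 54.7/125.3 degrees.
#'
#' @return data.frame with columns `label`, `phi`, `theta`.
#' @export
conformer_table <- function() {
  if (!is.null(.pucker_env$table)) return(.pucker_env$table)
  pat <- .conformer_patterns()
  rows <- lapply(names(pat), function(lab) {
    zj <- pat[[lab]]
    q2c <- sqrt(1 / 3) * sum(zj * cos(.ring_A2))
    q2s <- -sqrt(1 / 3) * sum(zj * sin(.ring_A2))
    q3 <- sqrt(1 / 6) * sum(zj * .ring_parity)
    Q <- sqrt(q2c^2 + q2s^2 + q3^2)
    phi <- if (q2c^2 + q2s^2 < 1e-20) 0 else (atan2(q2s, q2c) * 180 / pi) %% 360
    data.frame(label = lab, phi = phi,
               theta = acos(max(-1, min(1, q3 / Q))) * 180 / pi)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$label), ]
  rownames(tab) <- NULL
  .pucker_env$table <- tab
  tab
}

# alternate twist-boat descriptors (each skew has two equivalent names);
# literature-style aliases resolve to the canonical table entry
.conformer_aliases <- c("OS4" = "3S1", "4SO" = "1S3", "2S4" = "5S1",
                        "4S2" = "1S5", "3S5" = "OS2", "5S3" = "2SO")

.normalize_label <- function(label) {
  lab <- toupper(gsub("[^0-9A-Za-z]", "", label))
  if (lab %in% names(.conformer_aliases)) lab <- .conformer_aliases[[lab]]
  lab
}

#' Classify a pucker state into the canonical conformer vocabulary
#'
#' Returns the canonical label whose (phi, theta) vertex is nearest on the
#' unit puckering sphere (great-circle metric); ties break lexicographically
#' by label. Planar states return the `"planar"` sentinel.
#'
#' @param state a `pucker_state`, or a list with `phi`, `theta` in degrees
#'   (and optionally `planar`).
#' @param table a conformer table as from [conformer_table()].
#' @export
classify_conformer <- function(state, table = conformer_table()) {
  if (isTRUE(state$planar)) return("planar")
  stopifnot(is.finite(state$phi), is.finite(state$theta))
  d <- pucker_distance(state$phi, state$theta, table$phi, table$theta)
  # table is lexicographically sorted, so which.min implements the tie-break
  table$label[which.min(d)]
}

#' Great-circle distance on the puckering sphere
#' @param phi1,theta1,phi2,theta2 degrees; vectors recycle.
#' @return angular distance in degrees.
#' @export
pucker_distance <- function(phi1, theta1, phi2, theta2) {
  rad <- pi / 180
  cosd <- cos(theta1 * rad) * cos(theta2 * rad) +
    sin(theta1 * rad) * sin(theta2 * rad) * cos((phi1 - phi2) * rad)
  acos(pmax(-1, pmin(1, cosd))) / rad
}

#' Generate an ideal six-ring geometry at a canonical pucker
#'
#' Places a regular hexagon of edge 1.52 Å (clockwise when viewed from +z,
#' so the measured mean-plane normal is +z under the O5-first convention)
#' and adds out-of-plane displacements by inverting the Cremer–Pople mode
#' expansion at the canonical (phi, theta) of `label`:
#' \deqn{z_j = \sqrt{1/3}\, q_2 \cos(\phi_2 + 4\pi j/6)
#'        + \sqrt{1/6}\, q_3 (-1)^j,}
#' with \eqn{q_2 = Q\sin\theta}, \eqn{q_3 = Q\cos\theta}. At `noise = 0` the
#' measured (Q, phi, theta) equal the canonical values exactly, which is the
#' round-trip property the classification tests rely on. Bond lengths are
#' not controlled beyond staying in a chemically sane range; only
#' (Q, phi, theta) are observables downstream.
#'
#' @param label canonical conformer label (e.g. `"4C1"`, `"2SO"`, `"E3"`,
#'   `"B3,O"`; punctuation/aliases accepted) or `"planar"`.
#' @param Q total puckering amplitude, Å (ignored for `"planar"`). The
#'   default 0.57 Å is a typical pyranose chair amplitude.
#' @param seed integer seed for the noise draw.
#' @param noise isotropic Gaussian coordinate noise, Å.
#' @param edge hexagon edge length, Å.
#' @param frame frame identifier passed through.
#' @return a `ring_geometry`.
#' @export
generate_ring_conformer <- function(label, Q = 0.57, seed = 1, noise = 0,
                                    edge = 1.52, frame = NA) {
  stopifnot(Q >= 0, noise >= 0)
  lab <- .normalize_label(label)
  ang <- -.ring_A1  # clockwise
  pos <- cbind(edge * cos(ang), edge * sin(ang), 0)
  if (lab != "PLANAR") {
    tab <- conformer_table()
    hit <- match(lab, tab$label)
    if (is.na(hit)) stop(sprintf("unknown conformer label '%s'", label))
    rad <- pi / 180
    q2 <- Q * sin(tab$theta[hit] * rad)
    q3 <- Q * cos(tab$theta[hit] * rad)
    phi2 <- tab$phi[hit] * rad
    pos[, 3] <- sqrt(1 / 3) * q2 * cos(phi2 + .ring_A2) +
      sqrt(1 / 6) * q3 * .ring_parity
  }
  if (noise > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    pos <- pos + matrix(stats::rnorm(18, sd = noise), 6, 3)
  }
  ring_geometry(pos, frame = frame)
}

#' Puckering analysis of a ring trajectory
#'
#' Applies [cremer_pople()] to every frame and tabulates conformer-label
#' occupancy fractions (summing to 1). Geometry errors are re-raised with
#' the frame index attached.
#'
#' @param trajectory list of `ring_geometry` (or 6 x 3 matrices).
#' @param planarity_tol passed to [cremer_pople()].
#' @return list with `states` (list of `pucker_state`), `occupancy` (named
#'   numeric, fractions per label) and `table` (per-frame data.frame with
#'   frame, Q, phi, theta, conformer).
#' @export
pucker_series <- function(trajectory, planarity_tol = 0.01) {
  if (length(trajectory) == 0) stop("empty trajectory")
  states <- lapply(seq_along(trajectory), function(i) {
    tryCatch(cremer_pople(trajectory[[i]], planarity_tol = planarity_tol),
             error = function(e) {
               stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  labels <- vapply(states, `[[`, character(1), "conformer")
  occ <- table(labels) / length(labels)
  occupancy <- as.numeric(occ)
  names(occupancy) <- names(occ)
  tab <- data.frame(
    frame = seq_along(states),
    Q = vapply(states, `[[`, numeric(1), "Q"),
    phi = vapply(states, `[[`, numeric(1), "phi"),
    theta = vapply(states, `[[`, numeric(1), "theta"),
    conformer = labels)
  list(states = states, occupancy = occupancy, table = tab)
}
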