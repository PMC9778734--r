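#' Conformation set
#'
#' Cartesian coordinates of a fixed atom selection across frames — the
#' input of all RMSd and clustering machinery.
#'
#' @param frames list of n_atoms x 3 matrices (constant atom count), or a
#'   3D array frames x atoms x 3.
#' @param times frame times, ps (defaults to 1..n).
#' @param selection label of the clustered selection.
#' @return Object of class `conformation_set`.
#' @export
conformation_set <- function(frames, times = NULL, selection = "atoms") {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]),
                     function(i) frames[i, , , drop = TRUE])
  }
  stopifnot(is.list(frames), length(frames) >= 1)
  na <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) {
    is.matrix(f) && nrow(f) == na && ncol(f) == 3
  }, logical(1))
  if (!all(ok)) stop("all frames must be matrices with the same atom count")
  if (is.null(times)) times <- seq_along(frames)
  stopifnot(length(times) == length(frames))
  structure(list(frames = frames, times = as.numeric(times),
                 selection = selection, n_atoms = na),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat("<conformation_set> ", length(x$frames), " frames x ", x$n_atoms,
      " atoms (", x$selection, ")\n", sep = "")
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits `mobile` onto `reference`: centers both, finds the
#' optimal proper rotation from the SVD of the covariance matrix (with the
#' determinant sign correction so reflections are never applied), and
#' returns the transformed coordinates together with the minimal RMSd.
#'
#' @param mobile,reference n x 3 matrices, n >= 3, non-collinear.
#' @return list with `coords` (fitted mobile), `rmsd` (Å), `rotation`
#'   (3 x 3), `translation`.
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            nrow(mobile) == nrow(reference), ncol(mobile) == 3,
            ncol(reference) == 3)
  n <- nrow(mobile)
  if (n < 3) stop("superposition requires at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  if (max(svd(a)$d) < 1e-12 || sum(svd(a)$d > 1e-9 * max(svd(a)$d)) < 2) {
    stop("degenerate (collinear or coincident) atom set")
  }
  s <- svd(t(a) %*% b)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(sum((fitted - b)^2) / n)
  list(coords = sweep(fitted, 2, cr, "+"), rmsd = rmsd,
       rotation = rot, translation = cr - drop(rot %*% cm))
}

#' Plain (unfitted) RMSd between two coordinate sets
#' @param a,b n x 3 matrices.
#' @export
rmsd <- function(a, b) sqrt(sum((a - b)^2) / nrow(a))

#' RMSd of every frame to a reference
#'
#' @param set a `conformation_set`.
#' @param reference n_atoms x 3 matrix (or frame index into `set`).
#' @param fit superpose each frame on the reference first (default TRUE).
#' @return numeric vector, Å, one value per frame.
#' @export
rmsd_series <- function(set, reference, fit = TRUE) {
  stopifnot(inherits(set, "conformation_set"))
  if (length(reference) == 1 && is.numeric(reference)) {
    reference <- set$frames[[reference]]
  }
  if (nrow(reference) != set$n_atoms) {
    stop("reference atom count does not match the set")
  }
  vapply(set$frames, function(f) {
    if (fit) superpose(f, reference)$rmsd else rmsd(f, reference)
  }, numeric(1))
}

.pairwise_rmsd <- function(set, fit = TRUE) {
  n <- length(set$frames)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- if (fit) {
        superpose(set$frames[[j]], set$frames[[i]])$rmsd
      } else {
        rmsd(set$frames[[j]], set$frames[[i]])
      }
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Clustering result container
#' @keywords internal
.cluster_result <- function(assignment, centroids, cutoff = NA, k = NA,
                            method = "gromos") {
  n <- length(assignment)
  occ <- 100 * as.numeric(table(factor(assignment,
                                       levels = seq_along(centroids)))) / n
  structure(list(assignment = assignment, centroids = centroids,
                 occupancy = occ, cutoff = cutoff, k = k, method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$method, ": ", length(x$centroids),
      " cluster(s), occupancies ",
      paste(sprintf("%.1f%%", x$occupancy), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Gromos clustering of a conformation set
#'
#' The greedy neighbor-counting algorithm: for every unassigned frame count
#' neighbors within `cutoff` RMSd; the frame with most neighbors becomes a
#' centroid and it and its neighbors are removed; repeat until every frame
#' is assigned. Equal neighbor counts break toward the lower frame index,
#' making the result deterministic. A 1.2 Å cutoff on active-site heavy
#' atoms is the protocol default.
#'
#' @param set a `conformation_set`.
#' @param cutoff Å, > 0.
#' @param fit superpose each pair before the RMSd (default TRUE).
#' @return a `cluster_result` with per-frame assignments (cluster ids in
#'   discovery order), centroid frame indices and occupancy percentages.
#' @export
gromos_cluster <- function(set, cutoff = 1.2, fit = TRUE) {
  stopifnot(inherits(set, "conformation_set"), cutoff > 0)
  n <- length(set$frames)
  dm <- .pairwise_rmsd(set, fit = fit)
  neighbor <- dm <= cutoff          # includes self
  alive <- rep(TRUE, n)
  assignment <- integer(n)
  centroids <- integer(0)
  cl <- 0L
  while (any(alive)) {
    cl <- cl + 1L
    counts <- colSums(neighbor & alive)   # neighbors among remaining frames
    counts[!alive] <- -1L
    c_idx <- which.max(counts)            # ties -> lowest index
    members <- which(alive & neighbor[, c_idx])
    assignment[members] <- cl
    centroids[cl] <- c_idx
    alive[members] <- FALSE
  }
  .cluster_result(assignment, centroids, cutoff = cutoff, method = "gromos")
}

#' Occupancy-gated farthest-centroid seed selection
#'
#' The iterative-seeding rule for successive rounds of sampling: among
#' clusters whose occupancy strictly exceeds `occupancy_min` percent
#' (default 10%), pick the centroid with the largest fitted RMSd to the
#' starting structure; return `NULL` when no cluster qualifies.
#'
#' @param result a `cluster_result`.
#' @param set the clustered `conformation_set`.
#' @param start n_atoms x 3 matrix (or frame index) of the starting
#'   structure.
#' @param occupancy_min percent; the gate is strict (>, not >=).
#' @return list with `frame` (centroid index), `cluster`, `rmsd_to_start`,
#'   or `NULL`.
#' @export
select_seed <- function(result, set, start, occupancy_min = 10) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(set, "conformation_set"))
  if (length(start) == 1 && is.numeric(start)) start <- set$frames[[start]]
  eligible <- which(result$occupancy > occupancy_min)
  if (length(eligible) == 0) return(NULL)
  r <- vapply(eligible, function(cl) {
    superpose(set$frames[[result$centroids[cl]]], start)$rmsd
  }, numeric(1))
  best <- eligible[which.max(r)]
  list(frame = result$centroids[best], cluster = best,
       rmsd_to_start = max(r))
}

# deterministic k-means++ initialization: farthest-point flavored D^2 draw
.kmeanspp_init <- function(x, k, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x),
                              byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' Seeded k-means with nearest-to-mean representatives
#'
#' Standard Lloyd iteration in the supplied feature space (reaction
#' coordinate values, CV tuples, ...) with deterministic k-means++
#' initialization from `seed`. Empty clusters are re-seeded
#' deterministically with the point farthest from its assigned center. The
#' representative of each cluster is the member sample closest to the
#' cluster mean.
#'
#' @param samples `cv_series`, numeric vector or matrix (rows = samples).
#' @param k number of clusters, 1 <= k <= n samples.
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return a `cluster_result` (method `"kmeans"`); `centroids` are the
#'   representative sample indices, with cluster means in `$means` and the
#'   final within-cluster sum of squares in `$wss`.
#' @export
kmeans_representatives <- function(samples, k, seed = 1, max_iter = 100) {
  x <- if (inherits(samples, "cv_series")) samples$values else
    as.matrix(samples)
  n <- nrow(x)
  if (k <= 0) stop("k must be positive")
  if (k > n) stop("k exceeds the number of samples")
  centers <- .kmeanspp_init(x, k, seed)
  assignment <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j) {
      rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    new_assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {               # deterministic empty-cluster fix
      if (!any(new_assign == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_assign)])
        new_assign[far] <- j
      }
    }
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
    }
  }
  reps <- vapply(seq_len(k), function(j) {
    members <- which(assignment == j)
    d2m <- rowSums((x[members, , drop = FALSE] -
                    matrix(centers[j, ], length(members), ncol(x),
                           byrow = TRUE))^2)
    members[which.min(d2m)]
  }, integer(1))
  out <- .cluster_result(assignment, reps, k = k, method = "kmeans")
  out$means <- centers
  out$wss <- sum((x - centers[assignment, , drop = FALSE])^2)
  out
}
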