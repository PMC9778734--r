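#' Atom selections
#'
#' A labelled set of atom identifiers, resolvable against the atom table of
#' a trajectory. Identifiers are either flat 1-based indices or a filter on
#' the atom metadata columns (`name`, `resname`, `resid`, `chain`,
#' `element`), all given criteria combined with AND.
#'
#' @param label selection name.
#' @param indices integer atom indices (1-based), or NULL to use filters.
#' @param name,resname,resid,chain,element optional metadata filters
#'   (vectors allowed; a value matching any entry passes).
#' @return Object of class `atom_selection`.
#' @export
atom_selection <- function(label, indices = NULL, name = NULL,
                           resname = NULL, resid = NULL, chain = NULL,
                           element = NULL) {
  sel <- structure(list(label = label, indices = indices,
                        filters = list(name = name, resname = resname,
                                       resid = resid, chain = chain,
                                       element = element)),
                   class = "atom_selection")
  if (is.null(indices) && all(vapply(sel$filters, is.null, logical(1)))) {
    stop("atom_selection needs indices or at least one metadata filter")
  }
  sel
}

#' Resolve an atom selection to flat indices
#'
#' @param selection an `atom_selection` (bare integer vectors pass through).
#' @param atoms atom metadata data.frame (columns name, resname, resid,
#'   chain, element as available), one row per atom.
#' @return integer vector of 1-based atom indices.
#' @export
resolve_selection <- function(selection, atoms) {
  if (is.numeric(selection)) return(as.integer(selection))
  stopifnot(inherits(selection, "atom_selection"))
  if (!is.null(selection$indices)) {
    idx <- as.integer(selection$indices)
    if (any(idx < 1) || any(idx > nrow(atoms))) {
      stop(sprintf("selection '%s': index out of range", selection$label))
    }
    return(idx)
  }
  keep <- rep(TRUE, nrow(atoms))
  for (fld in names(selection$filters)) {
    val <- selection$filters[[fld]]
    if (is.null(val)) next
    if (!fld %in% names(atoms)) {
      stop(sprintf("selection '%s': atom table has no column '%s'",
                   selection$label, fld))
    }
    keep <- keep & (atoms[[fld]] %in% val)
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    stop(sprintf("selection '%s' resolves to no atoms", selection$label))
  }
  idx
}

#' Interatomic distance between two selections in one frame
#'
#' `mode = "single"` requires one atom per selection and returns their
#' Euclidean distance; `mode = "min_pair"` returns the minimum over the
#' a x b pair set — the convention used for heavy-atom hydrogen-bond
#' distances over donor/acceptor oxygen sets.
#'
#' @param frame n_atoms x 3 coordinate matrix, Å.
#' @param a,b resolved index vectors (or `atom_selection` plus `atoms`).
#' @param mode `"single"` or `"min_pair"`.
#' @param atoms atom metadata (needed only if a/b are `atom_selection`).
#' @return distance, Å.
#' @export
pair_distance <- function(frame, a, b, mode = c("single", "min_pair"),
                          atoms = NULL) {
  mode <- match.arg(mode)
  if (inherits(a, "atom_selection")) a <- resolve_selection(a, atoms)
  if (inherits(b, "atom_selection")) b <- resolve_selection(b, atoms)
  if (length(a) == 0 || length(b) == 0) stop("empty pair set")
  if (mode == "single") {
    if (length(a) != 1 || length(b) != 1) {
      stop("mode 'single' requires one atom per selection")
    }
    return(sqrt(sum((frame[a, ] - frame[b, ])^2)))
  }
  pa <- frame[a, , drop = FALSE]
  pb <- frame[b, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(max(0, min(d2)))
}

#' Nearest-solvent distance (d_Glu233-WAT, d_glyc-WAT machinery)
#'
#' Minimum distance from any target atom to any solvent reference atom,
#' together with the identity (residue id) of the solvent molecule that
#' attains it. Solvent identity is frame-wise: the nearest water, not a
#' tracked molecule.
#'
#' @param frame n_atoms x 3 coordinate matrix, Å.
#' @param target,solvent resolved index vectors or `atom_selection`s.
#' @param atoms atom metadata; required to resolve selections and to report
#'   the solvent residue id (falls back to the atom index).
#' @return list with `distance` (Å; `Inf` with `molecule = NA` when the
#'   solvent set is empty), `molecule`, `atom` (index of nearest solvent
#'   atom).
#' @export
nearest_solvent_distance <- function(frame, target, solvent, atoms = NULL) {
  if (inherits(target, "atom_selection")) {
    target <- resolve_selection(target, atoms)
  }
  solvent_empty <- FALSE
  if (inherits(solvent, "atom_selection")) {
    solvent <- tryCatch(resolve_selection(solvent, atoms),
                        error = function(e) integer(0))
  }
  if (length(solvent) == 0) {
    return(list(distance = Inf, molecule = NA, atom = NA_integer_,
                no_solvent = TRUE))
  }
  pt <- frame[target, , drop = FALSE]
  ps <- frame[solvent, , drop = FALSE]
  d2 <- outer(rowSums(pt^2), rowSums(ps^2), "+") - 2 * pt %*% t(ps)
  j <- which(d2 == min(d2), arr.ind = TRUE)[1, 2]
  mol <- if (!is.null(atoms) && "resid" %in% names(atoms)) {
    atoms$resid[solvent[j]]
  } else {
    solvent[j]
  }
  list(distance = sqrt(max(0, min(d2))), molecule = mol,
       atom = solvent[j], no_solvent = FALSE)
}

.check_finite_nonneg <- function(...) {
  for (v in list(...)) {
    if (any(!is.finite(v))) stop("non-finite distance input")
    if (any(v < 0)) stop("distances must be nonnegative")
  }
}

#' Glycosylation reaction coordinate d_glyc - d_acid
#'
#' The scalar reaction coordinate combining glycosidic-bond stretching with
#' the proton transfer from the catalytic acid: negative on the reactant
#' side, positive on the product side.
#'
#' @param d_glyc,d_acid distances, Å (vectors recycle).
#' @return RC values, Å.
#' @export
reaction_coordinate <- function(d_glyc, d_acid) {
  .check_finite_nonneg(d_glyc, d_acid)
  d_glyc - d_acid
}

#' Active-site compactness variable d_acid + d_nuc + d_Glu233-WAT
#' @param d_acid,d_nuc,d_Glu233_WAT distances, Å.
#' @return d_actsite, Å.
#' @export
d_actsite <- function(d_acid, d_nuc, d_Glu233_WAT) {
  .check_finite_nonneg(d_acid, d_nuc, d_Glu233_WAT)
  d_acid + d_nuc + d_Glu233_WAT
}

#' Monotone reactive-conformation variable d_acid - d_glyc-WAT + d_nuc
#' @param d_acid,d_glyc_WAT,d_nuc distances, Å.
#' @return composite CV, Å.
#' @export
d_react <- function(d_acid, d_glyc_WAT, d_nuc) {
  .check_finite_nonneg(d_acid, d_glyc_WAT, d_nuc)
  d_acid - d_glyc_WAT + d_nuc
}

#' Contact occupancy: fraction of frames below a distance cutoff
#'
#' @param distances per-frame minimum distances, Å.
#' @param cutoff Å, > 0 (3.5 Å is the usual close-contact criterion).
#' @return list with `fraction`, `count`, `total`.
#' @export
contact_occupancy <- function(distances, cutoff = 3.5) {
  if (length(distances) == 0) stop("empty distance series")
  stopifnot(cutoff > 0)
  n <- sum(distances < cutoff)
  list(fraction = n / length(distances), count = n,
       total = length(distances))
}
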