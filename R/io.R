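#' Read and write collective-variable tables
#'
#' Plain tab-separated text with a commented header line
#' `# time_ps <label1> <label2> ...` and one frame per row — the shape of
#' the raw CV tables deposited with umbrella-sampling studies. Writing then
#' reading is the identity at the stated precision.
#'
#' @param path file path.
#' @param temperature K, attached to the resulting series.
#' @return `read_cv_table`: a `cv_series`.
#' @export
read_cv_table <- function(path, temperature = default_temperature) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty CV table: ", path)
  header <- lines[1]
  if (!grepl("^#", header)) stop("CV table must start with a '# time_ps ...' header")
  labels <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "\\s+")
  ncol_exp <- length(labels)
  vals <- matrix(NA_real_, length(rows), ncol_exp)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_exp) {
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   i + 1, path, ncol_exp, length(rows[[i]])))
    }
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(v))) {
      stop(sprintf("line %d of %s: non-numeric cell", i + 1, path))
    }
    vals[i, ] <- v
  }
  if (labels[1] != "time_ps") {
    stop("first CV-table column must be time_ps")
  }
  cv_series(vals[, 1], vals[, -1, drop = FALSE], temperature = temperature,
            labels = labels[-1])
}

#' @rdname read_cv_table
#' @param series a `cv_series`.
#' @param digits significant digits written.
#' @export
write_cv_table <- function(series, path, digits = 10) {
  stopifnot(inherits(series, "cv_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(c("time_ps", colnames(series$values)),
                              collapse = "\t")), con)
  body <- cbind(series$times, series$values)
  utils::write.table(signif(body, digits), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a free-energy profile as tab-separated text
#'
#' 1D: columns bin_center, dG, mass, empty; 2D: one row per bin pair.
#' Empty bins are written with dG = `Inf` and flag `empty = TRUE`.
#'
#' @param profile a `free_energy_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  df <- as.data.frame(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- trajectories -----------------------------------------------------------

#' Read a coordinate trajectory (multi-model PDB or XYZ)
#'
#' Minimal readers for the two plain-text trajectory formats the package
#' writes. PDB: `MODEL`/`ENDMDL` blocks of fixed-column `ATOM`/`HETATM`
#' records; for altloc duplicates the first-seen variant of each atom is
#' kept and a warning is logged. XYZ: repeated `n / comment / n lines of
#' "element x y z"` blocks. Atom counts must be constant across models.
#' 1-based residue numbering is preserved as in the source.
#'
#' @param path file path.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @return Object of class `md_trajectory`: list with `coords` (list of
#'   n_atoms x 3 matrices), `atoms` (data.frame: serial, name, resname,
#'   chain, resid, element), `times` (frame index).
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") .read_pdb(path) else .read_xyz(path)
}

.read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(idx) {
    l <- lines[idx]
    altloc <- substr(l, 17, 17)
    key <- paste(trimws(substr(l, 13, 16)), substr(l, 22, 22),
                 trimws(substr(l, 23, 26)))
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("%s: %d altloc duplicate(s) dropped (first kept)",
                      path, sum(dup)))
      l <- l[!dup]; altloc <- altloc[!dup]
    }
    list(
      coords = cbind(as.numeric(substr(l, 31, 38)),
                     as.numeric(substr(l, 39, 46)),
                     as.numeric(substr(l, 47, 54))),
      atoms = data.frame(
        serial = suppressWarnings(as.integer(substr(l, 7, 11))),
        name = trimws(substr(l, 13, 16)),
        altloc = altloc,
        resname = trimws(substr(l, 18, 20)),
        chain = substr(l, 22, 22),
        resid = suppressWarnings(as.integer(substr(l, 23, 26))),
        element = trimws(substr(l, 77, 78))))
  }

  models <- unique(model_id[atom_lines])
  blocks <- lapply(models, function(m) {
    parse_block(atom_lines[model_id[atom_lines] == m])
  })
  na <- vapply(blocks, function(b) nrow(b$coords), integer(1))
  if (length(unique(na)) != 1) {
    stop("inconsistent atom counts across models in ", path)
  }
  if (any(!is.finite(unlist(lapply(blocks, `[[`, "coords"))))) {
    stop("unparseable coordinates in ", path)
  }
  structure(list(coords = lapply(blocks, `[[`, "coords"),
                 atoms = blocks[[1]]$atoms,
                 times = seq_along(blocks)),
            class = "md_trajectory")
}

.read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
  frames <- list(); atoms <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) stop("bad XYZ atom count at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated XYZ frame at line ", i)
    body <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    el <- vapply(body, `[[`, character(1), 1)
    xyz <- t(vapply(body, function(f) as.numeric(f[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("non-numeric XYZ coordinates near line ", i)
    if (is.null(atoms)) {
      atoms <- data.frame(serial = seq_len(n), name = el, altloc = " ",
                          resname = "MOL", chain = "A", resid = 1L,
                          element = el)
    } else if (n != nrow(atoms)) {
      stop("inconsistent atom counts across XYZ frames in ", path)
    }
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  structure(list(coords = frames, atoms = atoms,
                 times = seq_along(frames)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", length(x$coords), " frame(s) x ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a trajectory as multi-model PDB or XYZ
#'
#' @param traj an `md_trajectory`, or a list of ring geometries / coordinate
#'   matrices (atom metadata synthesized).
#' @param path output file.
#' @param format `"pdb"` or `"xyz"` (default by extension).
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!inherits(traj, "md_trajectory")) traj <- .as_trajectory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (i in seq_along(traj$coords)) {
      writeLines(c(as.character(nrow(traj$atoms)),
                   paste("frame", i)), con)
      xyz <- traj$coords[[i]]
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", traj$atoms$element,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else {
    a <- traj$atoms
    for (i in seq_along(traj$coords)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      xyz <- traj$coords[[i]]
      writeLines(sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        a$serial, a$name, " ", a$resname, a$chain, a$resid,
        xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

# coerce ring geometries / bare matrices into a trajectory
.as_trajectory <- function(frames) {
  if (inherits(frames, "ring_geometry")) frames <- list(frames)
  coords <- lapply(frames, function(f) {
    if (inherits(f, "ring_geometry")) f$positions else as.matrix(f)
  })
  na <- nrow(coords[[1]])
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  nm <- if (na == 6) ring_names else paste0("X", seq_len(na))
  el <- substr(nm, 1, 1)
  structure(list(coords = coords,
                 atoms = data.frame(serial = seq_len(na), name = nm,
                                    altloc = " ", resname = "RNG",
                                    chain = "A", resid = 1L, element = el),
                 times = seq_along(coords)),
            class = "md_trajectory")
}
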