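# Internal-coordinate topology and evaluation.
#
# Topology (bonds, angles, dihedrals) is frozen from the first frame of a
# trajectory: MD snapshots can transiently bring non-bonded atoms inside
# the distance cutoff, so connectivity detected on the geometry-optimized
# structure is assigned once to atom identifiers and reused for every
# frame.

#' Detect chemical bonds on a single frame
#'
#' All unordered atom pairs closer than `cutoff` are taken as bonds.  The
#' default 1.5 Angstrom keeps typical C-H, O-H, C-C (aromatic/radical),
#' C-O and O-O bonds and excludes non-bonded contacts for small organic
#' radicals; it is configurable because e.g. relaxed sp3 C-C bonds
#' (~1.54 Angstrom) fall outside it.
#'
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param cutoff bond distance cutoff, Angstrom (> 0).
#' @return integer matrix with columns `i`, `j` (1-based, i < j), ordered
#'   lexicographically.  Atoms of degree 0 trigger a warning.
#' @export
detect_bonds <- function(coords, cutoff = 1.5) {
  stopifnot(cutoff > 0)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  bonds <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  storage.mode(bonds) <- "integer"
  deg <- tabulate(c(bonds), nbins = n)
  if (any(deg == 0))
    warnf("atom(s) with no bond under cutoff %.2f A: %s", cutoff,
          paste(which(deg == 0), collapse = ", "))
  bonds
}

#' Enumerate bond angles from connectivity
#'
#' One angle (i, j, k) with vertex j for every unordered pair of
#' neighbors of every atom of degree >= 2, i.e. choose(degree, 2) angles
#' per atom.
#'
#' @param bonds bond matrix from [detect_bonds()].
#' @param n_atoms number of atoms.
#' @return integer matrix with columns `i`, `j`, `k` (vertex `j`, i < k).
#' @export
enumerate_angles <- function(bonds, n_atoms) {
  nb <- neighbor_list(bonds, n_atoms)
  out <- list()
  for (j in seq_len(n_atoms)) {
    nbs <- nb[[j]]
    if (length(nbs) < 2) next
    prs <- utils::combn(sort(nbs), 2)
    out[[length(out) + 1L]] <- cbind(prs[1, ], j, prs[2, ])
  }
  ang <- if (length(out)) do.call(rbind, out) else
    matrix(integer(), 0, 3)
  colnames(ang) <- c("i", "j", "k")
  ang
}

#' Select one dihedral per central bond
#'
#' For every bond (b, c) whose two endpoints each have at least one other
#' neighbor, exactly one torsion quadruple (a, b, c, d) is kept: all
#' quadruples sharing a central bond are strongly correlated along an MD
#' trajectory, so a single representative suffices.  Terminal atoms are
#' chosen deterministically: `a` is the lowest-index neighbor of `b`
#' excluding `c`, `d` the lowest-index neighbor of `c` excluding `b`; if
#' that gives a == d (three-membered ring) `d` advances to the next-lowest
#' index, and the bond is skipped when no a != d choice exists.
#'
#' @param bonds bond matrix from [detect_bonds()].
#' @param n_atoms number of atoms.
#' @return integer matrix with columns `a`, `b`, `c`, `d`.
#' @export
select_dihedrals <- function(bonds, n_atoms) {
  nb <- neighbor_list(bonds, n_atoms)
  out <- list()
  for (r in seq_len(nrow(bonds))) {
    b <- bonds[r, 1]; cc <- bonds[r, 2]
    a_cands <- sort(setdiff(nb[[b]], cc))
    d_cands <- sort(setdiff(nb[[cc]], b))
    if (!length(a_cands) || !length(d_cands)) next
    a <- a_cands[1]
    d <- d_cands[1]
    if (a == d) {
      if (length(d_cands) >= 2) d <- d_cands[2] else next
    }
    out[[length(out) + 1L]] <- c(a, b, cc, d)
  }
  dih <- if (length(out)) do.call(rbind, out) else
    matrix(integer(), 0, 4)
  colnames(dih) <- c("a", "b", "c", "d")
  dih
}

neighbor_list <- function(bonds, n_atoms) {
  nb <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Build the internal-coordinate topology of a trajectory
#'
#' Applies [detect_bonds()] to the first frame (the geometry-optimized
#' structure) and derives angles and dihedrals from the resulting
#' connectivity.
#'
#' @param traj an [xyz_trajectory()] (or a single n x 3 coordinate matrix
#'   together with `elements`).
#' @param cutoff bond cutoff, Angstrom.
#' @param elements element symbols when `traj` is a bare matrix.
#' @return an object of class `ic_topology`: fields `bonds`, `angles`,
#'   `dihedrals` (index matrices), `labels` (per-parameter names built
#'   from atom labels, e.g. `C1H1`, `H1C1H2`), `kind`
#'   (`"B"`/`"A"`/`"D"`), `atom_labels`, `elements`, `cutoff`.
#' @export
ic_topology <- function(traj, cutoff = 1.5, elements = NULL) {
  if (inherits(traj, "xyz_trajectory")) {
    coords <- traj$coords[[1]]
    elements <- traj$elements
  } else {
    coords <- as.matrix(traj)
    if (is.null(elements)) stopf("elements required for bare coordinates")
  }
  labels <- atom_labels(elements)
  n <- length(elements)
  bonds <- detect_bonds(coords, cutoff)
  angles <- enumerate_angles(bonds, n)
  dihedrals <- select_dihedrals(bonds, n)
  lab_b <- apply(bonds, 1, function(x) paste0(labels[x], collapse = ""))
  lab_a <- apply(angles, 1, function(x) paste0(labels[x], collapse = ""))
  lab_d <- apply(dihedrals, 1, function(x) paste0(labels[x], collapse = ""))
  structure(
    list(bonds = bonds, angles = angles, dihedrals = dihedrals,
         labels = c(lab_b, lab_a, lab_d),
         kind = rep(c("B", "A", "D"),
                    c(nrow(bonds), nrow(angles), nrow(dihedrals))),
         atom_labels = labels, elements = elements, cutoff = cutoff),
    class = "ic_topology")
}

#' @export
print.ic_topology <- function(x, ...) {
  cat(sprintf(
    "Internal-coordinate topology (cutoff %.2f A): %d bonds, %d angles, %d dihedrals\n",
    x$cutoff, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  cat("  bonds:    ", paste(x$labels[x$kind == "B"], collapse = " "), "\n")
  cat("  angles:   ", paste(x$labels[x$kind == "A"], collapse = " "), "\n")
  cat("  dihedrals:", paste(x$labels[x$kind == "D"], collapse = " "), "\n")
  invisible(x)
}

#' Evaluate internal coordinates on every frame
#'
#' Computes bond lengths (Angstrom), bond angles (degrees, \[0, 180\])
#' and signed dihedrals (degrees, (-180, 180\]) for every frame of a
#' trajectory under a fixed topology.  Degenerate geometry (collinear
#' dihedral backbone, zero-length arm) raises an error naming the frame
#' rather than silently emitting NaN, so corrupted frames are visible.
#'
#' @param traj an [xyz_trajectory()]; its first frame must be the one the
#'   topology was built from.
#' @param topology an [ic_topology()].
#' @return object of class `ic_series`: `values` (frames x parameters
#'   matrix, columns named by `topology$labels`), `kind`, `frame_ids`,
#'   `topology`.
#' @export
evaluate_series <- function(traj, topology) {
  stopifnot(inherits(traj, "xyz_trajectory"), inherits(topology, "ic_topology"))
  nf <- n_frames(traj)
  nb <- nrow(topology$bonds)
  na_ <- nrow(topology$angles)
  nd <- nrow(topology$dihedrals)
  vals <- matrix(NA_real_, nf, nb + na_ + nd,
                 dimnames = list(NULL, topology$labels))
  for (f in seq_len(nf)) {
    m <- traj$coords[[f]]
    if (nb) {
      d <- m[topology$bonds[, 1], , drop = FALSE] -
        m[topology$bonds[, 2], , drop = FALSE]
      vals[f, seq_len(nb)] <- sqrt(rowSums(d * d))
    }
    res <- tryCatch({
      ang <- if (na_) vapply(seq_len(na_), function(r) {
        ijk <- topology$angles[r, ]
        bond_angle(m[ijk[1], ], m[ijk[2], ], m[ijk[3], ])
      }, 0) else numeric()
      dih <- if (nd) vapply(seq_len(nd), function(r) {
        q <- topology$dihedrals[r, ]
        dihedral_angle(m[q[1], ], m[q[2], ], m[q[3], ], m[q[4], ])
      }, 0) else numeric()
      list(ang = ang, dih = dih)
    }, error = function(e) stopf("frame %d: %s", f, conditionMessage(e)))
    if (na_) vals[f, nb + seq_len(na_)] <- res$ang
    if (nd) vals[f, nb + na_ + seq_len(nd)] <- res$dih
  }
  structure(
    list(values = vals, kind = topology$kind,
         frame_ids = seq_len(nf), topology = topology),
    class = "ic_series")
}

#' @export
print.ic_series <- function(x, ...) {
  cat(sprintf("Internal-coordinate series: %d frames x %d parameters (%d B, %d A, %d D)\n",
              nrow(x$values), ncol(x$values), sum(x$kind == "B"),
              sum(x$kind == "A"), sum(x$kind == "D")))
  invisible(x)
}

#' Write a topology report
#'
#' Human-readable text listing bonds, angles and dihedrals with their
#' atom labels and index tuples, plus the cutoff; a JSON sidecar with the
#' same content is written next to it when `json = TRUE`.
#'
#' @param topology an [ic_topology()].
#' @param path output text path.
#' @param json also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(topology, path, json = TRUE) {
  stopifnot(inherits(topology, "ic_topology"))
  con <- textConnection("rpt", "w", local = TRUE)
  sink(con); print(topology); sink()
  close(con)
  writeLines(rpt, path, useBytes = TRUE)
  if (json) {
    jsonlite::write_json(
      list(cutoff = topology$cutoff,
           atom_labels = topology$atom_labels,
           n_bonds = nrow(topology$bonds),
           n_angles = nrow(topology$angles),
           n_dihedrals = nrow(topology$dihedrals),
           bonds = topology$bonds, angles = topology$angles,
           dihedrals = topology$dihedrals,
           labels = topology$labels, kind = topology$kind),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Export an internal-coordinate series as a delimited table
#'
#' One row per frame, a `frame` column plus one column per parameter.
#'
#' @param series an `ic_series`.
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path, sep = "\t") {
  stopifnot(inherits(series, "ic_series"))
  df <- data.frame(frame = series$frame_ids, series$values,
                   check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
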