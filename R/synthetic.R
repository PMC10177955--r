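# Synthetic study systems: idealized radical geometries, sinusoidal
# internal-coordinate trajectories rebuilt to Cartesian frames, and
# hyperfine responses with planted feature dependencies.  This module
# stands in for the quantum-chemistry stage (geometry optimization,
# ab initio MD, DFT hyperfine tensors) so the statistical pipeline can be
# exercised and validated against known ground truth.

#' Idealized radical geometries
#'
#' Constructs a chemically sensible single-frame structure for one of
#' four organic radicals, with all bonded distances below and all
#' non-bonded distances above the 1.5 Angstrom bond cutoff:
#'
#' * `methyl` (CH3): planar, C-H 1.08 A, atom order C1 H1 H2 H3.
#' * `ethyl` (CH2CH3): radical center C1 (H1, H2), methyl C2 (H3-H5),
#'   C-C 1.49 A.
#' * `methyl_peroxy` (CH3OO): C1 O1 O2 H1-H3, C-O 1.44 A, O-O 1.31 A.
#' * `semiquinone` (p-benzosemiquinone): 6 ring carbons C1-C6 (C1 carries
#'   the carbonyl-type O1, C6 the hydroxyl O2-H5), ring hydrogens H1-H4
#'   on C2-C5; 13 atoms.
#'
#' @param name radical name.
#' @return single-frame [xyz_trajectory()].
#' @export
make_idealized_geometry <- function(name = c("methyl", "ethyl",
                                             "methyl_peroxy",
                                             "semiquinone")) {
  name <- match.arg(name)
  deg2rad <- pi / 180
  if (name == "methyl") {
    elements <- c("C", "H", "H", "H")
    ang <- c(90, 210, 330) * deg2rad
    coords <- rbind(c(0, 0, 0),
                    cbind(1.08 * cos(ang), 1.08 * sin(ang), 0))
  } else if (name == "ethyl") {
    elements <- c("C", "C", "H", "H", "H", "H", "H")
    c1 <- c(0, 0, 0)
    c2 <- c(1.49, 0, 0)
    # alpha hydrogens on the planar radical center, 120 deg from C2
    h1 <- c1 + 1.08 * c(cos(120 * deg2rad), sin(120 * deg2rad), 0)
    h2 <- c1 + 1.08 * c(cos(-120 * deg2rad), sin(-120 * deg2rad), 0)
    # beta hydrogens: C1-C2-H 111 deg, staggered torsions 60/180/300
    beta <- lapply(c(60, 180, 300), function(phi)
      place_nerf(c2, c1, h1, 1.09, 111, phi))
    coords <- rbind(c1, c2, h1, h2, do.call(rbind, beta))
  } else if (name == "methyl_peroxy") {
    elements <- c("C", "O", "O", "H", "H", "H")
    c1 <- c(0, 0, 0)
    o1 <- c(1.44, 0, 0)
    o2 <- place_nerf(o1, c1, c(0, 1, 0), 1.31, 111, 0)
    hs <- lapply(c(60, 180, 300), function(phi)
      place_nerf(c1, o1, o2, 1.09, 110, phi))
    coords <- rbind(c1, o1, o2, do.call(rbind, hs))
  } else {
    elements <- c(rep("C", 6), "O", "O", rep("H", 5))
    # hexagon traversal order C1 C2 C4 C6 C5 C3, radius = aromatic C-C
    hex_order <- c(1, 2, 4, 6, 5, 3)
    th <- (90 + 60 * (seq_len(6) - 1)) * deg2rad
    ring <- matrix(0, 6, 3)
    ring[hex_order, ] <- cbind(1.40 * cos(th), 1.40 * sin(th), 0)
    radial <- ring / 1.40  # unit outward direction per ring atom
    o1 <- ring[1, ] + 1.26 * radial[1, ]   # carbonyl-type C1=O1
    o2 <- ring[6, ] + 1.36 * radial[6, ]   # hydroxyl C6-O2
    h5 <- place_nerf(o2, ring[6, ], ring[4, ], 0.97, 109, 0)  # in-plane O2-H5
    ring_h <- ring[2:5, ] + 1.08 * radial[2:5, ]
    coords <- rbind(ring, o1, o2, ring_h, h5)
  }
  xyz_trajectory(elements, list(coords),
                 comments = sprintf("idealized %s radical (synthetic)", name))
}

#' Ground truth for synthetic data
#'
#' Bundles the oscillation model of the fake MD stage and the planted
#' feature dependencies of the fake hyperfine stage.
#'
#' Each driven internal coordinate follows
#' `base + sum_m a_m sin(2 pi f_m t + phase_m) + N(0, jitter)`, a
#' superposition of `n_components` sine waves with Gaussian jitter.  The
#' default total amplitudes (bonds 0.1 A, angles 8 deg) mimic mid-range
#' MD spreads for small organic radicals; coordinates moving atoms that
#' sit on a ring are scaled by `ring_scale` since collective ring modes
#' are much stiffer than terminal bond/angle motion (and large ring
#' amplitudes would break the ring-closure topology).
#'
#' @param dependencies data frame with columns `nucleus`, `component`
#'   (`A_x`/`A_y`/`A_z`), `feature` (a feature label), `coef`; responses
#'   are linear combinations of the named feature columns.  May be
#'   empty (pure-noise responses).
#' @param noise_sd Gaussian noise standard deviation added to every
#'   response (MHz-scale; default 0.1).
#' @param bond_amp,angle_amp,dihedral_amp total oscillation amplitudes
#'   (Angstrom / degrees / degrees).
#' @param bond_jitter,angle_jitter,dihedral_jitter per-frame Gaussian
#'   jitter standard deviations.
#' @param n_components sinusoids per coordinate.
#' @param freq_range frequency range, cycles per frame.
#' @param ring_scale amplitude scale factor for ring-atom coordinates.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(dependencies = NULL, noise_sd = 0.1,
                         bond_amp = 0.1, angle_amp = 8, dihedral_amp = 10,
                         bond_jitter = 0.005, angle_jitter = 0.4,
                         dihedral_jitter = 0.5, n_components = 3L,
                         freq_range = c(0.02, 0.25), ring_scale = 0.3) {
  if (is.null(dependencies))
    dependencies <- data.frame(nucleus = character(), component = character(),
                               feature = character(), coef = numeric(),
                               stringsAsFactors = FALSE)
  stopifnot(all(c("nucleus", "component", "feature", "coef") %in%
                  names(dependencies)),
            noise_sd >= 0, bond_amp >= 0, angle_amp >= 0, dihedral_amp >= 0,
            bond_jitter >= 0, angle_jitter >= 0, dihedral_jitter >= 0)
  bad <- setdiff(dependencies$component, c("A_x", "A_y", "A_z"))
  if (length(bad))
    stopf("dependencies may target A_x/A_y/A_z only (A_iso is derived), not: %s",
          paste(unique(bad), collapse = ", "))
  structure(list(dependencies = dependencies, noise_sd = noise_sd,
                 amp = c(bond = bond_amp, angle = angle_amp,
                         dihedral = dihedral_amp),
                 jitter = c(bond = bond_jitter, angle = angle_jitter,
                            dihedral = dihedral_jitter),
                 n_components = as.integer(n_components),
                 freq_range = freq_range, ring_scale = ring_scale),
            class = "ground_truth")
}

# One oscillating coordinate series: base + sum of sinusoids + jitter.
osc_series <- function(n_frames, base, amp, jitter, n_components,
                       freq_range) {
  t <- seq_len(n_frames) - 1L
  v <- rep(base, n_frames)
  if (amp > 0 && n_components > 0) {
    a <- runif(n_components)
    a <- a / sum(a) * amp
    f <- runif(n_components, freq_range[1], freq_range[2])
    ph <- runif(n_components, 0, 2 * pi)
    for (m in seq_len(n_components))
      v <- v + a[m] * sin(2 * pi * f[m] * t + ph[m])
  }
  if (jitter > 0) v <- v + rnorm(n_frames, 0, jitter)
  v
}

#' Simulate a sinusoidal-dynamics trajectory
#'
#' Drives the internal coordinates of a spanning-tree Z-matrix of the
#' input structure with superposed sine waves plus Gaussian jitter
#' ([ground_truth()] oscillation spec) and rebuilds Cartesian frames by
#' sequential NeRF placement along a breadth-first construction tree
#' rooted at the highest-degree atom.  Every rebuilt frame is
#' Kabsch-aligned onto the input structure, so zero amplitude and jitter
#' reproduce the input exactly.  After building, bond topology is
#' re-extracted from every frame and must equal the input topology;
#' amplitudes that break it raise an error advising smaller values.
#'
#' Validation modes: with `validate = "structure"` (default) every frame
#' must keep all frame-0 bonds intact (bonded distance within
#' \[0.7 Angstrom, cutoff + 0.35 Angstrom\]) and all non-bonded pairs
#' clash-free (> 1.2 Angstrom); transient non-bonded contacts inside the
#' cutoff are allowed, since that is exactly why downstream analysis
#' freezes topology at frame 0.  `validate = "topology"` additionally
#' demands that per-frame bond re-extraction reproduces the frame-0 bond
#' set exactly -- stricter than realistic dynamics whenever a bond
#' length oscillates near the cutoff (e.g. a 1.49 Angstrom C-C bond
#' under a 1.5 Angstrom cutoff).
#'
#' @param frame0 single-frame [xyz_trajectory()] (the relaxed structure).
#' @param truth a [ground_truth()].
#' @param n_frames number of frames to generate.
#' @param seed integer seed; equal seeds give bit-identical trajectories.
#' @param cutoff bond cutoff used for topology freezing and validation.
#' @param validate `"structure"` (default), `"topology"`, or `"none"`.
#' @return an [xyz_trajectory()] of `n_frames` frames.
#' @export
simulate_trajectory <- function(frame0, truth = ground_truth(),
                                n_frames = 500, seed = NULL, cutoff = 1.5,
                                validate = c("structure", "topology",
                                             "none")) {
  validate <- match.arg(validate)
  stopifnot(inherits(frame0, "xyz_trajectory"), n_frames >= 1)
  ref <- frame0$coords[[1]]
  n <- nrow(ref)
  bonds <- detect_bonds(ref, cutoff)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  deg <- igraph::degree(g)
  root <- which.max(deg)  # ties resolved to the lowest index
  bfs <- igraph::bfs(g, root = root, father = TRUE, order = TRUE)
  ord <- as.integer(bfs$order)
  parent <- as.integer(bfs$father)
  if (anyNA(ord) || length(ord) < n)
    stopf("disconnected structure: simulate each component separately")
  # ring membership: atoms incident to a non-bridge edge move less
  bridges <- igraph::bridges(g)
  ring_edge <- setdiff(seq_len(igraph::ecount(g)), as.integer(bridges))
  in_ring <- rep(FALSE, n)
  if (length(ring_edge)) {
    ends <- igraph::ends(g, ring_edge)
    in_ring[as.integer(ends)] <- TRUE
  }

  # reference atoms for NeRF placement, in construction order
  placed <- integer(0)
  refs <- vector("list", n)   # per atom: list(p, q, s) or fewer
  for (k in seq_along(ord)) {
    a <- ord[k]
    if (k == 1) {
      refs[[a]] <- list()
    } else {
      p <- parent[a]
      if (k == 2) {
        refs[[a]] <- list(p = p)
      } else {
        q <- parent[p]
        if (is.na(q) || q == a) q <- setdiff(placed, c(a, p))[1]
        if (k == 3) {
          refs[[a]] <- list(p = p, q = q)
        } else {
          s <- parent[q]
          if (is.na(s) || s %in% c(a, p, q))
            s <- setdiff(placed, c(a, p, q))[1]
          refs[[a]] <- list(p = p, q = q, s = s)
        }
      }
    }
    placed <- c(placed, a)
  }

  with_seed(seed, {
    # per-atom driven internal coordinates
    series <- vector("list", n)
    for (k in seq_along(ord)) {
      a <- ord[k]
      rf <- refs[[a]]
      if (!length(rf)) next
      scale <- if (in_ring[a]) truth$ring_scale else 1
      sr <- list()
      sr$r <- osc_series(n_frames, vnorm(ref[a, ] - ref[rf$p, ]),
                         truth$amp["bond"] * scale,
                         truth$jitter["bond"] * scale,
                         truth$n_components, truth$freq_range)
      if (!is.null(rf$q)) {
        sr$theta <- osc_series(n_frames,
                               bond_angle(ref[a, ], ref[rf$p, ], ref[rf$q, ]),
                               truth$amp["angle"] * scale,
                               truth$jitter["angle"] * scale,
                               truth$n_components, truth$freq_range)
      }
      if (!is.null(rf$s)) {
        sr$phi <- osc_series(n_frames,
                             dihedral_angle(ref[a, ], ref[rf$p, ],
                                            ref[rf$q, ], ref[rf$s, ]),
                             truth$amp["dihedral"] * scale,
                             truth$jitter["dihedral"] * scale,
                             truth$n_components, truth$freq_range)
      }
      series[[a]] <- sr
    }

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      m <- matrix(NA_real_, n, 3)
      for (k in seq_along(ord)) {
        a <- ord[k]
        rf <- refs[[a]]
        if (k == 1) {
          m[a, ] <- c(0, 0, 0)
        } else if (k == 2) {
          m[a, ] <- m[rf$p, ] + c(series[[a]]$r[f], 0, 0)
        } else if (k == 3) {
          th <- series[[a]]$theta[f] * pi / 180
          u <- m[rf$q, ] - m[rf$p, ]
          u <- u / vnorm(u)
          # any perpendicular in-plane direction; azimuth is free here
          v <- cross3(u, c(0, 0, 1))
          if (vnorm(v) < 1e-8) v <- cross3(u, c(0, 1, 0))
          v <- v / vnorm(v)
          m[a, ] <- m[rf$p, ] + series[[a]]$r[f] *
            (cos(th) * u + sin(th) * v)
        } else {
          m[a, ] <- place_nerf(m[rf$p, ], m[rf$q, ], m[rf$s, ],
                               series[[a]]$r[f], series[[a]]$theta[f],
                               series[[a]]$phi[f])
        }
      }
      frames[[f]] <- kabsch_align(m, ref)
    }
    out <- xyz_trajectory(frame0$elements, frames,
                          comments = sprintf("synthetic frame %d",
                                             seq_len(n_frames)))
    if (validate != "none") {
      ref_key <- paste(bonds[, 1], bonds[, 2])
      bonded <- matrix(FALSE, n, n)
      bonded[bonds] <- TRUE
      bonded <- bonded | t(bonded)
      nonbonded_ut <- upper.tri(bonded) & !bonded
      for (f in seq_len(n_frames)) {
        dm <- as.matrix(stats::dist(out$coords[[f]]))
        bl <- dm[bonds]
        if (any(bl > cutoff + 0.35 | bl < 0.7))
          stopf(paste("frame %d: a frame-0 bond left the structural",
                      "range; reduce oscillation amplitudes"), f)
        if (any(dm[nonbonded_ut] < 1.2))
          stopf(paste("frame %d: non-bonded atoms clash;",
                      "reduce oscillation amplitudes"), f)
        if (validate == "topology") {
          bf <- suppressWarnings(detect_bonds(out$coords[[f]], cutoff))
          if (!identical(paste(bf[, 1], bf[, 2]), ref_key))
            stopf(paste("frame %d: re-extracted bond topology differs",
                        "from frame 0; reduce oscillation amplitudes"), f)
        }
      }
    }
    out
  })
}

#' Simulate hyperfine responses with planted dependencies
#'
#' Each response column (`A_x`, `A_y`, `A_z` per nucleus) is the linear
#' combination of feature columns declared in the ground truth plus
#' Gaussian noise; components without planted signal are pure noise.
#' The isotropic component is always derived downstream as the mean of
#' the three principal values, never emitted.
#'
#' @param features a [feature_table()] whose columns the dependency map
#'   references.
#' @param truth a [ground_truth()].
#' @param nuclei nucleus labels to emit; defaults to every nucleus named
#'   in the dependency map, or to all atoms of the feature table's
#'   source topology when the map is empty.
#' @param seed integer seed.
#' @return an [hf_responses()] set covering `features$snapshot_ids`.
#' @export
simulate_responses <- function(features, truth = ground_truth(),
                               nuclei = NULL, seed = NULL) {
  stopifnot(inherits(features, "feature_table"),
            inherits(truth, "ground_truth"))
  dep <- truth$dependencies
  dangling <- setdiff(dep$feature, features$labels)
  if (length(dangling))
    stopf("dependency references unknown feature(s): %s",
          paste(unique(dangling), collapse = ", "))
  if (is.null(nuclei)) {
    nuclei <- unique(dep$nucleus)
    if (!length(nuclei))
      stopf("no nuclei: supply `nuclei` or a non-empty dependency map")
  }
  ns <- nrow(features$matrix)
  with_seed(seed, {
    recs <- list()
    for (nuc in nuclei) {
      comp_vals <- sapply(c("A_x", "A_y", "A_z"), function(comp) {
        y <- rnorm(ns, 0, truth$noise_sd)
        rows <- dep[dep$nucleus == nuc & dep$component == comp, ,
                    drop = FALSE]
        for (r in seq_len(nrow(rows)))
          y <- y + rows$coef[r] * features$matrix[, rows$feature[r]]
        y
      })
      recs[[length(recs) + 1L]] <- data.frame(
        snapshot = features$snapshot_ids, nucleus = nuc,
        A_x = comp_vals[, "A_x"], A_y = comp_vals[, "A_y"],
        A_z = comp_vals[, "A_z"], stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, recs)
    hf_responses(all$snapshot, all$nucleus, all$A_x, all$A_y, all$A_z)
  })
}

#' Symmetric planted dependencies for a methyl-type radical
#'
#' Builds a [ground_truth()] dependency map in which each hydrogen's
#' principal components depend on its own bond length and on the
#' opposite angle with identical coefficients under relabeling, and the
#' central nucleus depends equally on all three bonds -- the magnetic
#' equivalence pattern expected for CH3.  Used to drive the symmetry
#' descriptors toward zero as sampling grows.
#'
#' @param features a [feature_table()] from the methyl topology.
#' @param hydrogens,center atom labels.
#' @param bond_coef,angle_coef planted coefficients.
#' @param ... further arguments passed to [ground_truth()].
#' @return a [ground_truth()].
#' @export
methyl_symmetric_truth <- function(features, hydrogens = c("H1", "H2", "H3"),
                                   center = "C1", bond_coef = -1,
                                   angle_coef = 0.7, ...) {
  labels <- features$labels
  kind <- features$kind
  bond_idx <- which(kind == "B")
  angle_idx <- which(kind == "A")
  dep <- list()
  for (h in hydrogens) {
    own <- labels[bond_idx][label_has_atom(labels[bond_idx], h)]
    opp <- labels[angle_idx][!label_has_atom(labels[angle_idx], h)]
    for (comp in c("A_x", "A_y", "A_z")) {
      dep[[length(dep) + 1L]] <- data.frame(
        nucleus = h, component = comp,
        feature = c(own, opp), coef = c(bond_coef, angle_coef),
        stringsAsFactors = FALSE)
    }
  }
  for (comp in c("A_x", "A_y", "A_z")) {
    dep[[length(dep) + 1L]] <- data.frame(
      nucleus = center, component = comp,
      feature = labels[bond_idx], coef = bond_coef,
      stringsAsFactors = FALSE)
  }
  ground_truth(dependencies = do.call(rbind, dep), ...)
}
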