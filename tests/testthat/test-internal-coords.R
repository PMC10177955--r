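# Topology construction and internal-coordinate evaluation.

test_that("bond detection respects the cutoff and flags isolated atoms", {
  # two atoms beyond the cutoff: no bonds, isolated-atom warning
  expect_warning(b <- detect_bonds(rbind(c(0, 0, 0), c(2, 0, 0))),
                 "no bond")
  expect_equal(nrow(b), 0)
  # a 1.54 A bond is only found with an enlarged cutoff
  cc <- rbind(c(0, 0, 0), c(1.54, 0, 0))
  expect_warning(expect_equal(nrow(detect_bonds(cc, 1.5)), 0))
  expect_equal(nrow(detect_bonds(cc, 1.6)), 1)
})

test_that("angle and dihedral enumeration agree with brute force on random graphs", {
  with_test_seed(42, {
    for (rep in 1:25) {
      n <- sample(4:12, 1)
      extra <- sample(0:3, 1)
      is_tree <- extra == 0
      bonds <- random_molecule_graph(n, extra = extra)
      bonded <- matrix(FALSE, n, n)
      bonded[bonds] <- TRUE
      bonded <- bonded | t(bonded)

      angles <- enumerate_angles(bonds, n)
      # brute force: all ordered triples i<k with both bonded to vertex j
      brute_angles <- 0L
      for (j in 1:n) for (i in 1:n) for (k in 1:n)
        if (i < k && i != j && k != j && bonded[i, j] && bonded[k, j])
          brute_angles <- brute_angles + 1L
      expect_equal(nrow(angles), brute_angles)
      deg <- rowSums(bonded)
      expect_equal(nrow(angles), sum(choose(deg, 2)))

      dihedrals <- select_dihedrals(bonds, n)
      # brute force under the deterministic tie-break: a is fixed to the
      # lowest-index neighbor of b, so the bond contributes iff some
      # d != a remains on the c side (3-ring degeneracies drop out)
      brute_central <- 0L
      plain_central <- 0L
      for (r in seq_len(nrow(bonds))) {
        b <- bonds[r, 1]; cc <- bonds[r, 2]
        as_ <- setdiff(which(bonded[b, ]), cc)
        ds_ <- setdiff(which(bonded[cc, ]), b)
        if (length(as_) && length(ds_)) {
          plain_central <- plain_central + 1L
          if (length(setdiff(ds_, min(as_))))
            brute_central <- brute_central + 1L
        }
      }
      expect_equal(nrow(dihedrals), brute_central)
      if (is_tree) expect_equal(nrow(dihedrals), plain_central)
      if (nrow(dihedrals)) {
        # exactly one dihedral per central pair; chain consecutively bonded
        expect_false(anyDuplicated(paste(dihedrals[, 2], dihedrals[, 3])) > 0)
        for (r in seq_len(nrow(dihedrals))) {
          q <- dihedrals[r, ]
          expect_true(bonded[q[1], q[2]] && bonded[q[2], q[3]] &&
                        bonded[q[3], q[4]])
          expect_true(q[1] != q[4])
        }
      }
    }
  })
})

test_that("bond angles match an independent cross-product formulation", {
  expect_equal(bond_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
  # dual-formula oracle: atan2(|u x v|, u . v)
  with_test_seed(7, {
    for (i in 1:1000) {
      p <- matrix(rnorm(9), 3, 3)
      u <- p[1, ] - p[2, ]
      v <- p[3, ] - p[2, ]
      cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      oracle <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
      expect_equal(bond_angle(p[1, ], p[2, ], p[3, ]), oracle,
                   tolerance = 1e-9)
    }
  })
})

test_that("dihedrals recover constructed torsions and stay in (-180, 180]", {
  # planar eclipsed and anti quadruples
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, -1, 0)), 180)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "degenerate")
  # rotating the far substituent about the c -> b axis by theta gives theta
  p_b <- c(0, 0, 0)
  p_c <- c(1.5, 0, 0)
  p_a <- c(-0.5, 1.1, 0)
  for (theta in c(30, -30, 120, -120)) {
    R <- rotation_about(p_b - p_c, theta)
    p_d <- p_c + as.numeric(R %*% c(0, 1.1, 0))
    expect_equal(dihedral_angle(p_a, p_b, p_c, p_d), theta,
                 tolerance = 1e-9)
  }
})

test_that("idealized topologies give the reference bond/angle/dihedral counts", {
  counts <- list(methyl = c(3, 3, 0), ethyl = c(6, 9, 1),
                 methyl_peroxy = c(5, 7, 1), semiquinone = c(13, 19, 7))
  for (nm in names(counts)) {
    topo <- ic_topology(make_idealized_geometry(nm))
    expect_equal(c(nrow(topo$bonds), nrow(topo$angles),
                   nrow(topo$dihedrals)), counts[[nm]],
                 info = nm)
  }
})

test_that("series evaluation is self-consistent and rigid-motion invariant", {
  tr <- simulate_trajectory(make_idealized_geometry("ethyl"),
                            n_frames = 8, seed = 5)
  topo <- ic_topology(tr)
  ser <- evaluate_series(tr, topo)
  expect_equal(ncol(ser$values), 6 + 9 + 1)
  expect_true(all(is.finite(ser$values)))
  a_cols <- ser$kind == "A"
  d_cols <- ser$kind == "D"
  expect_true(all(ser$values[, a_cols] >= 0 & ser$values[, a_cols] <= 180))
  expect_true(all(ser$values[, d_cols] > -180 & ser$values[, d_cols] <= 180))

  # frame-0 bond lengths of the idealized geometry match construction
  topo_m <- ic_topology(make_idealized_geometry("methyl"))
  ser_m <- evaluate_series(make_idealized_geometry("methyl"), topo_m)
  expect_equal(unname(ser_m$values[1, topo_m$kind == "B"]), rep(1.08, 3),
               tolerance = 1e-9)
  expect_equal(unname(ser_m$values[1, topo_m$kind == "A"]), rep(120, 3),
               tolerance = 1e-9)

  # global rotation + translation leaves every value unchanged
  R <- rotation_about(c(1, 2, 0.5), 77)
  shift <- c(3, -2, 11)
  rot <- xyz_trajectory(tr$elements, lapply(tr$coords, function(m)
    sweep(m %*% t(R), 2, shift, `+`)))
  ser_rot <- evaluate_series(rot, topo)
  expect_equal(ser_rot$values, ser$values, tolerance = 1e-9)
})

test_that("semiquinone spans 39 structure parameters", {
  tr <- make_idealized_geometry("semiquinone")
  topo <- ic_topology(tr)
  expect_equal(length(tr$elements), 13)
  ser <- evaluate_series(tr, topo)
  expect_equal(ncol(ser$values), 39)
})
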