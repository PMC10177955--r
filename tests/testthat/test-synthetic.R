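# Synthetic geometries, sinusoidal trajectories, planted responses.

test_that("idealized geometries are chemically sensible under the cutoff", {
  specs <- list(methyl = 4, ethyl = 7, methyl_peroxy = 6, semiquinone = 13)
  for (nm in names(specs)) {
    tr <- make_idealized_geometry(nm)
    expect_length(tr$elements, specs[[nm]])
    m <- tr$coords[[1]]
    dm <- as.matrix(dist(m))
    bonds <- detect_bonds(m)
    bonded <- matrix(FALSE, nrow(m), nrow(m))
    bonded[bonds] <- TRUE
    bonded <- bonded | t(bonded)
    # bonded pairs < 1.5 A, all others > 1.5 A
    expect_true(all(dm[bonded] < 1.5), info = nm)
    nb <- upper.tri(dm) & !bonded
    expect_true(all(dm[nb] > 1.5), info = nm)
  }
  expect_error(make_idealized_geometry("benzene"))

  # methyl: planar with C at the centroid of the hydrogens
  m <- make_idealized_geometry("methyl")$coords[[1]]
  expect_equal(as.numeric(colMeans(m[2:4, ])), as.numeric(m[1, ]),
               tolerance = 1e-9)
  expect_equal(max(abs(m[, 3])), 0)
})

test_that("zero-amplitude simulation reproduces the input frame exactly", {
  still <- ground_truth(bond_amp = 0, angle_amp = 0, dihedral_amp = 0,
                        bond_jitter = 0, angle_jitter = 0,
                        dihedral_jitter = 0)
  for (nm in c("methyl", "semiquinone")) {
    f0 <- make_idealized_geometry(nm)
    tr <- simulate_trajectory(f0, still, n_frames = 4, seed = 1)
    for (f in 1:4)
      expect_equal(tr$coords[[f]], f0$coords[[1]], tolerance = 1e-9)
  }
})

test_that("simulation is seed-reproducible and preserves structure", {
  f0 <- make_idealized_geometry("ethyl")
  t1 <- simulate_trajectory(f0, n_frames = 30, seed = 12)
  t2 <- simulate_trajectory(f0, n_frames = 30, seed = 12)
  expect_identical(t1$coords, t2$coords)
  t3 <- simulate_trajectory(f0, n_frames = 30, seed = 13)
  expect_false(identical(t1$coords, t3$coords))

  # frame-0 topology is reproducible from every generated frame's bonds
  topo0 <- ic_topology(f0)
  ser <- evaluate_series(t1, ic_topology(t1))
  expect_true(all(is.finite(ser$values)))
  expect_identical(ic_topology(t1)$bonds, topo0$bonds)

  # absurd amplitudes must be caught
  wild <- ground_truth(bond_amp = 3, angle_amp = 60)
  expect_error(simulate_trajectory(f0, wild, n_frames = 10, seed = 1),
               "amplitudes")

  # the strict re-extraction mode holds for methyl at default amplitudes
  expect_s3_class(simulate_trajectory(make_idealized_geometry("methyl"),
                                      n_frames = 50, seed = 3,
                                      validate = "topology"),
                  "xyz_trajectory")
})

test_that("a programmed single sinusoid is recovered from the rebuilt frames", {
  truth <- ground_truth(n_components = 1, bond_jitter = 0,
                        angle_jitter = 0, dihedral_jitter = 0)
  tr <- simulate_trajectory(make_idealized_geometry("methyl"), truth,
                            n_frames = 400, seed = 17)
  ser <- evaluate_series(tr, ic_topology(tr))
  s <- ser$values[, 1]  # a C-H bond-length series, driven directly
  t <- seq_along(s) - 1
  # single-frequency least squares: coarse grid, then local refinement
  rss_at <- function(f) sum(resid(lm(s ~ sin(2 * pi * f * t) +
                                       cos(2 * pi * f * t)))^2)
  grid <- seq(0.015, 0.26, by = 2e-4)
  f0 <- grid[which.min(vapply(grid, rss_at, 0))]
  f_hat <- optimize(rss_at, c(f0 - 2e-4, f0 + 2e-4))$minimum
  fit <- lm(s ~ sin(2 * pi * f_hat * t) + cos(2 * pi * f_hat * t))
  amp_hat <- sqrt(sum(coef(fit)[2:3]^2))
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(abs(amp_hat - 0.1) / 0.1, 0.02)   # amplitude within 2 %
})

test_that("planted responses follow the declared linear model", {
  ft <- manual_feature_table(2000, c("fa", "fb", "fc"), seed = 61)
  # zero noise, single dependency with coefficient 1 -> exact copy
  dep1 <- data.frame(nucleus = "H1", component = "A_x", feature = "fb",
                     coef = 1, stringsAsFactors = FALSE)
  r0 <- simulate_responses(ft, ground_truth(dependencies = dep1,
                                            noise_sd = 0), seed = 1)
  expect_equal(r0$A_x[r0$nucleus == "H1"], unname(ft$matrix[, "fb"]))

  # variance algebra: sd(response) ~ sqrt(sum c^2 var + noise^2)
  dep2 <- data.frame(nucleus = "H1", component = rep("A_x", 2),
                     feature = c("fa", "fc"), coef = c(1.5, -0.8),
                     stringsAsFactors = FALSE)
  r2 <- simulate_responses(ft, ground_truth(dependencies = dep2,
                                            noise_sd = 0.5), seed = 2)
  v_fa <- var(ft$matrix[, "fa"])
  v_fc <- var(ft$matrix[, "fc"])
  expected_sd <- sqrt(1.5^2 * v_fa + 0.8^2 * v_fc + 0.5^2)
  expect_lt(abs(sd(r2$A_x[r2$nucleus == "H1"]) - expected_sd) / expected_sd,
            0.05)

  # seeded reproducibility, and all three principal components emitted
  r2b <- simulate_responses(ft, ground_truth(dependencies = dep2,
                                             noise_sd = 0.5), seed = 2)
  expect_identical(as.data.frame(r2), as.data.frame(r2b))
  expect_true(all(c("A_x", "A_y", "A_z") %in% names(r2)))

  # dangling feature label
  depx <- data.frame(nucleus = "H1", component = "A_x",
                     feature = "missing", coef = 1, stringsAsFactors = FALSE)
  expect_error(simulate_responses(ft, ground_truth(dependencies = depx),
                                  seed = 1), "unknown feature")
})
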