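# Shared fixtures, all generated in code.

# Random well-spread single-frame geometry (no bond structure implied).
random_coords <- function(n, scale = 3) {
  matrix(rnorm(3 * n, sd = scale), n, 3)
}

# Random connected molecular graph on n atoms: a random spanning tree
# plus `extra` random extra edges (possibly closing rings).
random_molecule_graph <- function(n, extra = 0) {
  edges <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1L, 1L), 0L))
  if (extra > 0) {
    all_pairs <- t(utils::combn(n, 2))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    cand <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), ,
                      drop = FALSE]
    if (nrow(cand))
      edges <- rbind(edges, cand[sample.int(nrow(cand),
                                            min(extra, nrow(cand))), ,
                                 drop = FALSE])
  }
  bonds <- cbind(i = pmin(edges[, 1], edges[, 2]),
                 j = pmax(edges[, 1], edges[, 2]))
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

# Minimal hand-built feature table (iid standard normal features).
manual_feature_table <- function(n, labels, seed = 1,
                                 kind = rep("B", length(labels))) {
  m <- with_test_seed(seed, matrix(rnorm(n * length(labels)), n,
                                   length(labels)))
  colnames(m) <- labels
  structure(
    list(matrix = m, labels = labels, kind = kind,
         snapshot_ids = seq_len(n), mode = "zscore",
         center = setNames(rep(0, length(labels)), labels),
         scale = setNames(rep(1, length(labels)), labels),
         dropped = character()),
    class = "feature_table")
}

# Minimal hand-built importance matrix.
manual_importance_matrix <- function(values, components, nuclei,
                                     feature_labels = NULL) {
  if (is.null(feature_labels))
    feature_labels <- paste0("f", seq_len(dim(values)[1]))
  dimnames(values) <- list(feature_labels, components, nuclei)
  structure(
    list(values = values, lambda = 0.05,
         feature_labels = feature_labels,
         feature_kind = rep("B", length(feature_labels)),
         component_labels = components, nucleus_labels = nuclei,
         converged = matrix(TRUE, length(components), length(nuclei)),
         seed = 1L),
    class = "importance_matrix")
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Rotation matrix about a unit axis (Rodrigues), used as the independent
# construction for dihedral tests.
rotation_about <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

methyl_feature_fixture <- function(n_frames = 60, seed = 1) {
  tr <- simulate_trajectory(make_idealized_geometry("methyl"),
                            n_frames = n_frames, seed = seed)
  ser <- evaluate_series(tr, ic_topology(tr))
  feature_table(ser)
}
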