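# Symmetry-based quality descriptors.
#
# Magnetically equivalent nuclei (e.g. the three methyl hydrogens) must
# show identical importance patterns once each nucleus' feature column is
# permuted into a shared canonical ordering; and for a symmetric center
# nucleus the entries of equivalent features (the three C-H bonds, the
# three H-C-H angles) must coincide.  Residual asymmetry gauges
# insufficient sampling statistics, so both descriptors act as
# data-quality diagnostics with exact-symmetry value 0.

#' Declare magnetic-equivalence structure
#'
#' @param groups named list of character vectors: nucleus labels expected
#'   magnetically equivalent (e.g. `list(CH3 = c("H1","H2","H3"))`).
#' @param permutations named list (one entry per group member label) of
#'   integer permutation vectors over feature indices; `perm[k]` is the
#'   feature index whose importance belongs at canonical slot `k` for
#'   that member.
#' @param blocks named list (per nucleus label) of lists of integer
#'   feature-index vectors expected mutually equivalent for that nucleus.
#' @return object of class `equivalence_spec`.
#' @export
equivalence_spec <- function(groups = list(), permutations = list(),
                             blocks = list()) {
  for (g in groups) {
    for (m in g) {
      perm <- permutations[[m]]
      if (is.null(perm)) stopf("no permutation declared for nucleus %s", m)
      if (length(perm) == 0 || !all(sort(as.integer(perm)) == seq_along(perm)))
        stopf("permutation for %s is not a bijection", m)
    }
  }
  for (nuc in names(blocks)) {
    idx <- unlist(blocks[[nuc]])
    if (anyDuplicated(idx))
      stopf("feature blocks for %s overlap", nuc)
  }
  structure(list(groups = groups, permutations = permutations,
                 blocks = blocks),
            class = "equivalence_spec")
}

#' Canonical equivalence spec for a methyl-type center
#'
#' For an XH3 center with hydrogens `hydrogens` bonded to `center`, the
#' canonical feature ordering per hydrogen HX is: slot 1 its own bond
#' HX-center, slots 2-3 the remaining bonds (ascending label), slot 4
#' the opposite angle (the one not involving HX), slots 5-6 the
#' remaining angles (ascending label).  Any further features keep their
#' original positions.  Feature blocks for the center nucleus are its
#' bond entries and its angle entries.
#'
#' @param features a [feature_table()] built from the methyl-type
#'   topology (bond columns first, then angle columns).
#' @param hydrogens labels of the three equivalent hydrogens.
#' @param center label of the central nucleus.
#' @param group_name name of the equivalence group.
#' @return an [equivalence_spec()].
#' @export
methyl_equivalence_spec <- function(features, hydrogens = c("H1", "H2", "H3"),
                                    center = "C1", group_name = "CH3") {
  stopifnot(inherits(features, "feature_table"))
  labels <- features$labels
  kind <- features$kind
  p <- length(labels)
  bond_idx <- which(kind == "B")
  angle_idx <- which(kind == "A")
  # bond feature of hydrogen h: the bond label containing both names
  own_bond <- vapply(hydrogens, function(h) {
    hit <- bond_idx[label_has_atom(labels[bond_idx], h) &
                    label_has_atom(labels[bond_idx], center)]
    if (length(hit) != 1) stopf("cannot identify bond %s-%s", h, center)
    hit
  }, 0L)
  opp_angle <- vapply(hydrogens, function(h) {
    hit <- angle_idx[!label_has_atom(labels[angle_idx], h)]
    if (length(hit) != 1)
      stopf("cannot identify the angle opposite %s", h)
    hit
  }, 0L)
  perms <- lapply(hydrogens, function(h) {
    perm <- seq_len(p)
    other_bonds <- setdiff(bond_idx, own_bond[h])
    other_angles <- setdiff(angle_idx, opp_angle[h])
    perm[bond_idx] <- c(own_bond[h], other_bonds[order(labels[other_bonds])])
    perm[angle_idx] <- c(opp_angle[h],
                         other_angles[order(labels[other_angles])])
    perm
  })
  names(perms) <- hydrogens
  blocks <- list()
  blocks[[center]] <- list(bonds = bond_idx, angles = angle_idx)
  equivalence_spec(groups = setNames(list(hydrogens), group_name),
                   permutations = perms, blocks = blocks)
}

# does a concatenated parameter label contain atom label `atom` at a
# token boundary (e.g. "C1H1" contains H1 and C1 but not H11)?
label_has_atom <- function(labels, atom) {
  vapply(labels, function(l) {
    toks <- regmatches(l, gregexpr("[A-Z][a-z]?[0-9]+", l))[[1]]
    atom %in% toks
  }, logical(1), USE.NAMES = FALSE)
}

#' Permutation-aligned cumulative MSE across equivalent nuclei
#'
#' Each group member's importance column is permuted into the canonical
#' ordering; for the chosen tensor components the mean squared difference
#' over features is computed for every unordered member pair and summed
#' (cumulatively) over pairs, components and groups.  Exactly symmetric
#' matrices give 0.
#'
#' @param imp an `importance_matrix`.
#' @param spec an [equivalence_spec()].
#' @param components tensor components entering the descriptor; the
#'   anisotropic principal values `A_x`, `A_y`, `A_z` by default.
#' @param aggregate `"sum"` (cumulative, default) or `"mean"` over the
#'   per-component contributions.
#' @return nonnegative scalar, with a `"per_component"` attribute giving
#'   the breakdown.
#' @export
group_mse_descriptor <- function(imp, spec,
                                 components = c("A_x", "A_y", "A_z"),
                                 aggregate = c("sum", "mean")) {
  stopifnot(inherits(imp, "importance_matrix"),
            inherits(spec, "equivalence_spec"))
  aggregate <- match.arg(aggregate)
  missing_comp <- setdiff(components, imp$component_labels)
  if (length(missing_comp))
    stopf("component(s) not in matrix: %s",
          paste(missing_comp, collapse = ", "))
  per_comp <- setNames(numeric(length(components)), components)
  for (g in spec$groups) {
    miss <- setdiff(g, imp$nucleus_labels)
    if (length(miss))
      stopf("unknown nucleus label(s): %s", paste(miss, collapse = ", "))
    for (comp in components) {
      aligned <- vapply(g, function(m) {
        perm <- spec$permutations[[m]]
        if (length(perm) != length(imp$feature_labels))
          stopf("permutation for %s does not cover all %d features",
                m, length(imp$feature_labels))
        imp$values[perm, comp, m]
      }, numeric(length(imp$feature_labels)))
      prs <- utils::combn(seq_along(g), 2)
      for (cc in seq_len(ncol(prs))) {
        diff <- aligned[, prs[1, cc]] - aligned[, prs[2, cc]]
        per_comp[comp] <- per_comp[comp] + mean(diff^2)
      }
    }
  }
  out <- if (aggregate == "sum") sum(per_comp) else mean(per_comp)
  attr(out, "per_component") <- per_comp
  out
}

#' Standard-deviation descriptor over equivalent feature blocks
#'
#' For one nucleus, the standard deviation of the importances inside each
#' declared block of mutually equivalent features is computed per tensor
#' component, and the overall mean over blocks and components is
#' returned.  Zero iff all entries agree within every block.
#'
#' @param imp an `importance_matrix`.
#' @param nucleus nucleus label (e.g. the central carbon).
#' @param blocks list of integer feature-index vectors (each of size
#'   >= 2); defaults to the blocks declared for `nucleus` in `spec`.
#' @param spec optional [equivalence_spec()] supplying `blocks`.
#' @param components tensor components, `A_x`/`A_y`/`A_z` by default.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return nonnegative scalar mean standard deviation.
#' @export
block_std_descriptor <- function(imp, nucleus, blocks = NULL, spec = NULL,
                                 components = c("A_x", "A_y", "A_z"),
                                 sd_type = c("sample", "population")) {
  stopifnot(inherits(imp, "importance_matrix"))
  sd_type <- match.arg(sd_type)
  if (is.null(blocks)) {
    if (is.null(spec)) stopf("supply blocks or a spec declaring them")
    blocks <- spec$blocks[[nucleus]]
    if (is.null(blocks)) stopf("no blocks declared for nucleus %s", nucleus)
  }
  if (!nucleus %in% imp$nucleus_labels)
    stopf("unknown nucleus label: %s", nucleus)
  missing_comp <- setdiff(components, imp$component_labels)
  if (length(missing_comp))
    stopf("component(s) not in matrix: %s",
          paste(missing_comp, collapse = ", "))
  sds <- numeric(0)
  for (blk in blocks) {
    if (length(blk) < 2) stopf("feature block of size < 2")
    if (any(blk < 1 | blk > length(imp$feature_labels)))
      stopf("block index out of range")
    for (comp in components) {
      v <- imp$values[blk, comp, nucleus]
      s <- sd(v)
      if (sd_type == "population")
        s <- s * sqrt((length(v) - 1) / length(v))
      sds <- c(sds, s)
    }
  }
  mean(sds)
}

#' Tabulate symmetry descriptors
#'
#' Convenience driver evaluating [group_mse_descriptor()] for every group
#' and [block_std_descriptor()] for every nucleus with declared blocks,
#' returning a tidy table (and optionally writing it).
#'
#' @param imp an `importance_matrix`.
#' @param spec an [equivalence_spec()].
#' @param components tensor components.
#' @param path optional output path for a delimited table.
#' @return data frame with columns `descriptor`, `target`, `components`,
#'   `value`.
#' @export
symmetry_descriptor_table <- function(imp, spec,
                                      components = c("A_x", "A_y", "A_z"),
                                      path = NULL) {
  rows <- list()
  for (gname in names(spec$groups)) {
    one <- equivalence_spec(groups = spec$groups[gname],
                            permutations = spec$permutations,
                            blocks = list())
    val <- group_mse_descriptor(imp, one, components = components)
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor = "group_mse", target = gname,
      components = paste(components, collapse = "+"),
      value = as.numeric(val), stringsAsFactors = FALSE)
  }
  for (nuc in names(spec$blocks)) {
    val <- block_std_descriptor(imp, nuc, blocks = spec$blocks[[nuc]],
                                components = components)
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor = "block_std", target = nuc,
      components = paste(components, collapse = "+"),
      value = as.numeric(val), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                fileEncoding = "UTF-8")
  out
}
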