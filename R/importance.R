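# Importance-matrix assembly: one NCA fit per (tensor component,
# nucleus), collected into a features x components x nuclei array.

#' Isotropic hyperfine component
#'
#' The rotation-invariant isotropic coupling, taken as the mean of the
#' three principal values (A_x + A_y + A_z) / 3 -- the standard
#' convention for reporting A_iso from a diagonalized hyperfine tensor.
#'
#' @param A_x,A_y,A_z numeric principal values (MHz); vectorized.
#' @return numeric A_iso, MHz.
#' @examples
#' compute_aiso(10, 20, 30)  # 20
#' @export
compute_aiso <- function(A_x, A_y, A_z) (A_x + A_y + A_z) / 3

HF_COMPONENTS <- c("A_x", "A_y", "A_z", "A_iso")

#' Build the per-molecule importance matrix
#'
#' Runs one independent regularized NCA fit for every requested hyperfine
#' component of every nucleus, under one shared lambda so importances are
#' comparable across the matrix.  Each fit gets a reproducible seed
#' derived from the base seed and a stable hash of its
#' (component, nucleus) labels.
#'
#' @param features a [feature_table()].
#' @param responses an [hf_responses()] set; its snapshot ids must match
#'   `features$snapshot_ids` exactly for every nucleus.
#' @param lambda shared regularization parameter (default 0.05).
#' @param config an [nca_config()].
#' @param seed base integer seed.
#' @param components subset of `c("A_x", "A_y", "A_z", "A_iso")`.
#' @return object of class `importance_matrix`: `values` (features x
#'   components x nuclei nonnegative array with dimnames), `lambda`,
#'   `feature_labels`, `feature_kind`, `component_labels`,
#'   `nucleus_labels`, `converged` (components x nuclei logical matrix),
#'   `seed`.
#' @export
build_importance_matrix <- function(features, responses, lambda = 0.05,
                                    config = nca_config(), seed = 1L,
                                    components = HF_COMPONENTS) {
  stopifnot(inherits(features, "feature_table"),
            inherits(responses, "hf_responses"))
  components <- match.arg(components, HF_COMPONENTS, several.ok = TRUE)
  if (!nrow(responses)) stopf("empty response set")
  nuclei <- unique(responses$nucleus)
  snap <- features$snapshot_ids
  p <- ncol(features$matrix)
  vals <- array(NA_real_, c(p, length(components), length(nuclei)),
                dimnames = list(features$labels, components, nuclei))
  conv <- matrix(NA, length(components), length(nuclei),
                 dimnames = list(components, nuclei))
  for (nuc in nuclei) {
    sub <- responses[responses$nucleus == nuc, , drop = FALSE]
    rows <- match(snap, sub$snapshot)
    if (any(is.na(rows))) {
      missing_ids <- snap[is.na(rows)]
      stopf("nucleus %s lacks response(s) for snapshot(s): %s", nuc,
            paste(utils::head(missing_ids, 10), collapse = ", "))
    }
    extra <- setdiff(sub$snapshot, snap)
    if (length(extra))
      stopf("nucleus %s has responses for snapshot(s) absent from the feature table: %s",
            nuc, paste(utils::head(extra, 10), collapse = ", "))
    sub <- sub[rows, , drop = FALSE]
    ys <- cbind(A_x = sub$A_x, A_y = sub$A_y, A_z = sub$A_z,
                A_iso = compute_aiso(sub$A_x, sub$A_y, sub$A_z))
    for (comp in components) {
      fit_seed <- (as.integer(seed) + label_hash(paste(comp, nuc))) %%
        2147483647L
      fit <- fit_nca(features$matrix, ys[, comp], lambda = lambda,
                     config = config, seed = fit_seed)
      vals[, comp, nuc] <- fit$importance
      conv[comp, nuc] <- fit$converged
    }
  }
  structure(
    list(values = vals, lambda = lambda,
         feature_labels = features$labels, feature_kind = features$kind,
         component_labels = components, nucleus_labels = nuclei,
         converged = conv, seed = seed),
    class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Importance matrix: %d features x %d components x %d nuclei (lambda = %g)\n",
    d[1], d[2], d[3], x$lambda))
  if (!all(x$converged))
    cat(sprintf("  %d of %d fits did not converge\n",
                sum(!x$converged), length(x$converged)))
  invisible(x)
}

#' Extract one component slice of an importance matrix
#'
#' @param imp an `importance_matrix`.
#' @param component one of its component labels (e.g. `"A_iso"`).
#' @return features x nuclei numeric matrix.
#' @export
importance_slice <- function(imp, component) {
  stopifnot(inherits(imp, "importance_matrix"))
  if (!component %in% imp$component_labels)
    stopf("unknown component '%s'", component)
  m <- imp$values[, component, , drop = FALSE]
  dim(m) <- dim(imp$values)[c(1, 3)]
  dimnames(m) <- list(imp$feature_labels, imp$nucleus_labels)
  m
}

#' Export an importance matrix as a long-format table
#'
#' Columns `feature`, `kind`, `component`, `nucleus`, `importance`; one
#' row per matrix entry.
#'
#' @param imp an `importance_matrix`.
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_importance_table <- function(imp, path, sep = "\t") {
  stopifnot(inherits(imp, "importance_matrix"))
  long <- expand.grid(feature = imp$feature_labels,
                      component = imp$component_labels,
                      nucleus = imp$nucleus_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$kind <- imp$feature_kind[match(long$feature, imp$feature_labels)]
  long$importance <- as.vector(imp$values)
  long <- long[c("feature", "kind", "component", "nucleus", "importance")]
  write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
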