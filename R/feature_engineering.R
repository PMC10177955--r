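# Feature engineering: dihedral trig expansion, optional angle-sum
# feature, per-feature standardization, randomized snapshot subsampling.

#' Expand dihedral columns to cosine/sine pairs
#'
#' Dihedrals are circular variables with a discontinuity at
#' 360 deg = 0 deg; encoding each as (cos, sin) makes them continuous.
#' Bond-length and bond-angle columns pass through unchanged (angles live
#' in \[0, 180\] and are pseudo-continuous).  Feature count becomes
#' n_bonds + n_angles + 2 * n_dihedrals.
#'
#' @param series an `ic_series` from [evaluate_series()].
#' @return list with `matrix` (frames x features), `labels`
#'   (`cos_<name>` / `sin_<name>` for dihedral pairs), `kind`
#'   (`B`/`A`/`Dcos`/`Dsin`).
#' @export
dihedral_to_trig <- function(series) {
  stopifnot(inherits(series, "ic_series"))
  v <- series$values
  keep <- series$kind != "D"
  cols <- list(v[, keep, drop = FALSE])
  labels <- colnames(v)[keep]
  kind <- series$kind[keep]
  for (ci in which(series$kind == "D")) {
    rad <- v[, ci] * pi / 180
    cols[[length(cols) + 1L]] <- cbind(cos(rad), sin(rad))
    labels <- c(labels, paste0(c("cos_", "sin_"), colnames(v)[ci]))
    kind <- c(kind, "Dcos", "Dsin")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- labels
  list(matrix = m, labels = labels, kind = kind)
}

#' Append the sum-of-angles feature
#'
#' The per-frame sum of all bond angles (degrees) gauges collective
#' planar-to-pyramidal distortion at trigonal centers: a planar XH3
#' center contributes 360 deg and any pyramidalization strictly lowers
#' its contribution.  Off by default in [feature_table()].
#'
#' @param expanded output of [dihedral_to_trig()].
#' @param series the originating `ic_series` (for the angle columns).
#' @return the `expanded` list with one extra column (kind `"S"`, label
#'   `"angle_sum"`) appended last.
#' @export
add_angle_sum <- function(expanded, series) {
  a_cols <- which(series$kind == "A")
  if (!length(a_cols)) stopf("no angle columns: angle-sum feature undefined")
  s <- rowSums(series$values[, a_cols, drop = FALSE])
  m <- cbind(expanded$matrix, angle_sum = s)
  list(matrix = m,
       labels = c(expanded$labels, "angle_sum"),
       kind = c(expanded$kind, "S"))
}

#' Standardize a feature matrix
#'
#' `zscore` (default) centers each column to zero mean and unit standard
#' deviation; `minmax` maps each column onto \[0, 1\].  Constant columns
#' carry no information and would divide by zero, so they are dropped
#' with a warning.  Parameters are recorded for the inverse transform.
#'
#' @param matrix frames x features numeric matrix.
#' @param mode `"zscore"` or `"minmax"`.
#' @return list `matrix`, `mode`, `center`, `scale`, `dropped` (labels of
#'   removed constant columns).  For minmax, `center` is the column min
#'   and `scale` the range.
#' @export
standardize <- function(matrix, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  if (nrow(matrix) < 2) stopf("standardization needs >= 2 rows")
  if (mode == "zscore") {
    center <- colMeans(matrix)
    scale_ <- apply(matrix, 2, sd)
  } else {
    center <- apply(matrix, 2, min)
    scale_ <- apply(matrix, 2, max) - center
  }
  const <- scale_ <= 0 | !is.finite(scale_)
  dropped <- colnames(matrix)[const]
  if (any(const)) {
    warnf("dropping constant feature column(s): %s",
          paste(dropped, collapse = ", "))
    matrix <- matrix[, !const, drop = FALSE]
    center <- center[!const]
    scale_ <- scale_[!const]
  }
  std <- sweep(sweep(matrix, 2, center), 2, scale_, `/`)
  list(matrix = std, mode = mode, center = center, scale = scale_,
       dropped = dropped)
}

#' Invert a standardization
#'
#' @param std list returned by [standardize()] (or a [feature_table()]).
#' @param matrix optionally a different standardized matrix to map back;
#'   defaults to `std$matrix`.
#' @return matrix on the original scale.
#' @export
unstandardize <- function(std, matrix = std$matrix) {
  sweep(sweep(matrix, 2, std$scale, `*`), 2, std$center, `+`)
}

#' Randomized snapshot subsampling
#'
#' Structure parameters oscillate as superpositions of near-regular sine
#' waves, so snapshots at a fixed stride would alias any normal mode
#' whose period matches the stride.  Gaps between consecutive snapshots
#' are therefore drawn i.i.d. uniform-integer from `interval`, starting
#' at the first frame and stopping past the last.
#'
#' @param n_frames total number of trajectory frames.
#' @param interval integer pair `c(lo, hi)`, 1 <= lo <= hi <= n_frames.
#'   Default `c(1, 80)`.
#' @param seed integer seed; equal seeds give identical draws.
#' @return strictly increasing integer vector of 1-based frame indices,
#'   starting at 1.
#' @export
subsample_snapshots <- function(n_frames, interval = c(1, 80), seed = NULL) {
  stopifnot(n_frames >= 1, length(interval) == 2)
  lo <- as.integer(interval[1]); hi <- as.integer(interval[2])
  if (lo < 1 || lo > hi) stopf("need 1 <= lo <= hi in interval")
  if (hi > n_frames)
    stopf("interval upper bound %d exceeds frame count %d", hi, n_frames)
  with_seed(seed, {
    ids <- integer(0)
    cur <- 1L
    while (cur <= n_frames) {
      ids <- c(ids, cur)
      cur <- cur + sample.int(hi - lo + 1L, 1L) + lo - 1L
    }
    ids
  })
}

#' Build a standardized NCA feature table
#'
#' Applies [dihedral_to_trig()], optionally [add_angle_sum()], restricts
#' to the chosen snapshots, and standardizes each feature individually.
#' Standardization happens after subsampling so the recorded statistics
#' describe exactly the analyzed set.
#'
#' @param series an `ic_series`.
#' @param snapshot_ids frame indices to keep (default: all frames), e.g.
#'   from [subsample_snapshots()].
#' @param angle_sum add the sum-of-angles feature (default `FALSE`).
#' @param mode standardization mode, see [standardize()].
#' @return object of class `feature_table`: `matrix` (snapshots x
#'   features, standardized), `labels`, `kind`, `snapshot_ids`, `mode`,
#'   `center`, `scale`, `dropped`.
#' @export
feature_table <- function(series, snapshot_ids = NULL, angle_sum = FALSE,
                          mode = c("zscore", "minmax")) {
  stopifnot(inherits(series, "ic_series"))
  mode <- match.arg(mode)
  exp_ <- dihedral_to_trig(series)
  if (angle_sum) exp_ <- add_angle_sum(exp_, series)
  if (is.null(snapshot_ids)) snapshot_ids <- series$frame_ids
  rows <- match(snapshot_ids, series$frame_ids)
  if (any(is.na(rows)))
    stopf("snapshot id(s) outside trajectory: %s",
          paste(snapshot_ids[is.na(rows)], collapse = ", "))
  m <- exp_$matrix[rows, , drop = FALSE]
  std <- standardize(m, mode)
  kept <- !(exp_$labels %in% std$dropped)
  structure(
    list(matrix = std$matrix, labels = exp_$labels[kept],
         kind = exp_$kind[kept], snapshot_ids = as.integer(snapshot_ids),
         mode = mode, center = std$center, scale = std$scale,
         dropped = std$dropped),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table: %d snapshots x %d features (%s standardized)\n",
    nrow(x$matrix), ncol(x$matrix), x$mode))
  tab <- table(factor(x$kind, levels = c("B", "A", "Dcos", "Dsin", "S")))
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (length(x$dropped))
    cat("  dropped constant:", paste(x$dropped, collapse = " "), "\n")
  invisible(x)
}

#' Export a feature table with a metadata sidecar
#'
#' Writes the standardized matrix as a delimited table (snapshot column
#' plus one column per feature) and `<path>.meta.json` holding mode,
#' per-feature parameters and provenance.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, sep = "\t") {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(snapshot = ft$snapshot_ids, ft$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(mode = ft$mode, labels = ft$labels, kind = ft$kind,
         center = ft$center, scale = ft$scale, dropped = ft$dropped),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
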