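# Multi-frame XYZ trajectory and hyperfine response table IO.
#
# The XYZ dialect is plain XYZ as emitted by quantum-chemistry MD codes:
# per frame an atom-count line, a free comment line (carried opaquely,
# never parsed), then one "El x y z" line per atom.  All frames must
# share the element sequence of frame 1, which is taken to be the
# geometry-optimized structure.

#' Construct a trajectory object
#'
#' @param elements character vector of element symbols (shared by all
#'   frames).
#' @param coords list of n_atoms x 3 numeric matrices, one per frame
#'   (Angstrom).
#' @param comments character vector of per-frame comment lines.
#' @return an object of class `xyz_trajectory` with fields `elements`,
#'   `labels` (see [atom_labels()]), `coords`, `comments`.
#' @export
xyz_trajectory <- function(elements, coords, comments = NULL) {
  if (!length(coords)) stopf("a trajectory needs at least one frame")
  elements <- as.character(elements)
  bad <- setdiff(unique(elements), PERIODIC_TABLE)
  if (length(bad))
    stopf("unknown element symbol(s): %s", paste(bad, collapse = ", "))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3 || nrow(m) != length(elements))
      stopf("each frame must be a %d x 3 coordinate matrix", length(elements))
    if (!all(is.finite(m))) stopf("non-finite coordinates in frame")
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  if (is.null(comments)) comments <- rep("", length(coords))
  structure(
    list(elements = elements, labels = atom_labels(elements),
         coords = coords, comments = as.character(comments)),
    class = "xyz_trajectory")
}

#' @export
print.xyz_trajectory <- function(x, ...) {
  cat(sprintf("XYZ trajectory: %d frame(s), %d atoms (%s)\n",
              n_frames(x), length(x$elements),
              paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `xyz_trajectory`.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Read a multi-frame XYZ trajectory
#'
#' Parses a plain XYZ file (atom-count line, comment line, atom lines,
#' repeated).  Frames must all list the same elements in the same order;
#' the first frame defines the atom labeling.
#'
#' @param path path to an XYZ file.
#' @return an [xyz_trajectory()].
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stopf("empty XYZ file: %s", path)

  pos <- 1L
  frame_no <- 0L
  elements0 <- NULL
  coords <- list()
  comments <- character()
  while (pos <= length(lines)) {
    frame_no <- frame_no + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1)
      stopf("frame %d: malformed atom-count line '%s'", frame_no, lines[pos])
    if (pos + 1L + nat > length(lines))
      stopf("frame %d: declares %d atoms but file is truncated", frame_no, nat)
    comments <- c(comments, lines[pos + 1L])
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4))
      stopf("frame %d: malformed atom line %d", frame_no, which(nt < 4)[1])
    els <- vapply(toks, `[`, "", 1L)
    if (!all(els %in% PERIODIC_TABLE))
      stopf("frame %d: unknown element symbol '%s'", frame_no,
            els[!(els %in% PERIODIC_TABLE)][1])
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(xyz)))
      stopf("frame %d: non-numeric coordinate in atom line %d", frame_no,
            which(rowSums(!is.finite(xyz)) > 0)[1])
    if (is.null(elements0)) {
      elements0 <- els
    } else if (!identical(els, elements0)) {
      stopf("frame %d: element sequence differs from frame 1", frame_no)
    }
    coords[[frame_no]] <- xyz
    pos <- pos + 2L + nat
  }
  xyz_trajectory(elements0, coords, comments)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param traj an [xyz_trajectory()].
#' @param path output path (UTF-8).
#' @param digits coordinate decimals (default 6, the usual MD output
#'   precision).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "xyz_trajectory"))
  nat <- length(traj$elements)
  fmt <- sprintf("%%-2s %%15.%df %%15.%df %%15.%df", digits, digits, digits)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(nat), traj$comments[f]), con)
    m <- traj$coords[[f]]
    writeLines(sprintf(fmt, traj$elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Construct a hyperfine response set
#'
#' Per-snapshot, per-nucleus hyperfine principal values A_x, A_y, A_z
#' (MHz).  Stored as a data frame with class `hf_responses`.
#'
#' @param snapshot integer frame indices (1-based, referencing trajectory
#'   frames).
#' @param nucleus atom labels (`H1`, `C1`, ...).
#' @param A_x,A_y,A_z numeric principal values, MHz.
#' @return `hf_responses` data frame.
#' @export
hf_responses <- function(snapshot, nucleus, A_x, A_y, A_z) {
  df <- data.frame(snapshot = as.integer(snapshot),
                   nucleus = as.character(nucleus),
                   A_x = as.numeric(A_x), A_y = as.numeric(A_y),
                   A_z = as.numeric(A_z), stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[c("A_x", "A_y", "A_z")]))))
    stopf("non-finite hyperfine value")
  key <- paste(df$snapshot, df$nucleus)
  if (anyDuplicated(key))
    stopf("duplicate (snapshot, nucleus) record: %s",
          key[duplicated(key)][1])
  class(df) <- c("hf_responses", "data.frame")
  df
}

#' Read a hyperfine response table
#'
#' Delimited text with header columns `snapshot`, `nucleus`, `A_x`,
#' `A_y`, `A_z`; tab or comma delimiter auto-detected from the header
#' line.  Values are in MHz (units never enter the statistics).
#'
#' @param path path to the table.
#' @return an [hf_responses()] data frame.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snapshot", "nucleus", "A_x", "A_y", "A_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("response table %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  for (col in c("snapshot", "A_x", "A_y", "A_z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stopf("non-numeric value in column '%s', row %d", col,
            which(is.na(v))[1])
    df[[col]] <- v
  }
  hf_responses(df$snapshot, df$nucleus, df$A_x, df$A_y, df$A_z)
}

#' Write a hyperfine response table
#'
#' @param responses an [hf_responses()] data frame.
#' @param path output path.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(responses, path, sep = "\t") {
  stopifnot(inherits(responses, "hf_responses"))
  out <- as.data.frame(responses)
  # %.17g survives a text round trip bit-exactly
  for (col in c("A_x", "A_y", "A_z")) out[[col]] <- sprintf("%.17g", out[[col]])
  write.table(out, path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
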