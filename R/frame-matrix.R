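#' Conformation set as a frame-by-coordinate matrix
#'
#' An `ecs_frames` object stores a set of molecular conformations ("frames")
#' as an \eqn{N \times m} numeric matrix: one row per frame, and the
#' \eqn{m = 3 n_{atoms}} columns hold the flattened Cartesian coordinates
#' (x, y, z per atom, in Angstrom, in atom order).  This row-vector layout is
#' the common input of every similarity and selection routine in the package.
#'
#' @param values Numeric matrix (or data frame coercible to one), frames in
#'   rows, flattened coordinates in columns.  The column count must be a
#'   multiple of 3 and all entries finite.
#' @param frame_ids Integer identifiers for the frames, in source order.
#'   Defaults to `1:N` (frames are indexed 1-based throughout).
#' @param atom_labels Optional tibble with one row per atom and columns
#'   `residue` (integer) and `atom` (character atom name).  Synthesised as
#'   `X1..Xn` when absent (e.g. for plain matrix input).
#'
#' @return An object of class `ecs_frames` with elements `values`,
#'   `frame_ids`, `atom_labels`, `n_atoms`.
#' @examples
#' fm <- frame_matrix(rbind(c(0, 0, 0), c(1, 1, 1)))
#' fm$n_atoms
#' @export
frame_matrix <- function(values, frame_ids = NULL, atom_labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (frames x flattened coordinates).")
  }
  if (nrow(values) < 1L || ncol(values) < 3L) {
    abort("a frame matrix needs at least 1 frame and 3 coordinate columns.")
  }
  if (ncol(values) %% 3L != 0L) {
    abort(sprintf("column count (%d) must be divisible by 3 (x,y,z per atom).",
                  ncol(values)))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite coordinate at frame %d, column %d.",
                  bad[[1L]], bad[[2L]]))
  }
  n_atoms <- ncol(values) %/% 3L
  if (is.null(frame_ids)) frame_ids <- seq_len(nrow(values))
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != nrow(values)) {
    abort("`frame_ids` must have one entry per frame.")
  }
  if (is.null(atom_labels)) {
    atom_labels <- tibble::tibble(residue = seq_len(n_atoms),
                                  atom = paste0("X", seq_len(n_atoms)))
  }
  atom_labels <- tibble::as_tibble(atom_labels)
  if (nrow(atom_labels) != n_atoms) {
    abort(sprintf("`atom_labels` has %d rows but the matrix describes %d atoms.",
                  nrow(atom_labels), n_atoms))
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, frame_ids = frame_ids,
         atom_labels = atom_labels, n_atoms = n_atoms),
    class = "ecs_frames"
  )
}

#' Coerce to an `ecs_frames` object
#'
#' Accepts an existing `ecs_frames`, a numeric matrix or a data frame whose
#' rows are frames.
#'
#' @param x Object to coerce.
#' @return An `ecs_frames` object.
#' @export
as_frame_matrix <- function(x) {
  if (inherits(x, "ecs_frames")) return(x)
  if (inherits(x, "ecs_traj")) return(x$frames)
  frame_matrix(x)
}

#' @export
as.matrix.ecs_frames <- function(x, ...) x$values

#' @export
dim.ecs_frames <- function(x) dim(x$values)

#' @export
print.ecs_frames <- function(x, ...) {
  cat(sprintf("<ecs_frames> %d frames x %d atoms (%d coordinate columns)\n",
              nrow(x$values), x$n_atoms, ncol(x$values)))
  cat("atoms: ", paste(head(x$atom_labels$atom, 6L), collapse = " "),
      if (x$n_atoms > 6L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a frame matrix into long format
#'
#' One row per frame/atom/axis combination; convenient for ggplot2 work on
#' small systems.
#'
#' @param x An `ecs_frames` object.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `residue`, `atom`, `axis`, `value`.
#' @method tidy ecs_frames
#' @export
tidy.ecs_frames <- function(x, ...) {
  m <- ncol(x$values)
  tibble::tibble(
    frame   = rep(x$frame_ids, each = m),
    residue = rep(rep(x$atom_labels$residue, each = 3L), times = nrow(x$values)),
    atom    = rep(rep(x$atom_labels$atom, each = 3L), times = nrow(x$values)),
    axis    = rep(rep(c("x", "y", "z"), times = x$n_atoms), times = nrow(x$values)),
    value   = as.vector(t(x$values))
  )
}
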