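#' Read trajectory frames into a frame matrix
#'
#' Reads molecular-dynamics conformations from a multi-model PDB file
#' (frames as `MODEL`/`ENDMDL` blocks), an XYZ trajectory (repeated
#' count/comment/atom-line blocks) or a plain delimited coordinate matrix
#' (one frame per row, flattened x,y,z columns; the package's interchange
#' format).
#'
#' The default atom selection for structure formats is the protein backbone
#' (atoms named `N`, `CA`, `C`), the coordinate basis used throughout the
#' diversity-selection workflow.  Atom names are matched exactly after
#' whitespace stripping; for PDB input only blank or `A` alternate-location
#' indicators are kept, and heteroatoms/hydrogens are excluded by the name
#' filter alone.  The matrix format carries no atom names, so the selection
#' defaults to `"all"` there.
#'
#' @param path Path to the input file.
#' @param format One of `"pdb"`, `"xyz"`, `"matrix"`, or `"auto"` (guess from
#'   the file extension: `.pdb`, `.xyz`, anything else is read as a matrix).
#' @param atom_selection `"backbone"` (default for pdb/xyz), `"all"`, or a
#'   character vector of atom names to keep.
#' @return An [frame_matrix()] (`ecs_frames`) object; rows follow source order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("0,0,0", "1,1,1"), path)
#' read_frames(path)
#' @export
read_frames <- function(path, format = c("auto", "pdb", "xyz", "matrix"),
                        atom_selection = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pdb") "pdb" else if (ext == "xyz") "xyz" else "matrix"
  }
  if (is.null(atom_selection)) {
    atom_selection <- if (format == "matrix") "all" else "backbone"
  }
  switch(format,
    pdb    = read_frames_pdb(path, atom_selection),
    xyz    = read_frames_xyz(path, atom_selection),
    matrix = read_frames_matrix(path, atom_selection)
  )
}

backbone_names <- c("N", "CA", "C")

selection_names <- function(atom_selection) {
  if (identical(atom_selection, "backbone")) return(backbone_names)
  if (identical(atom_selection, "all")) return(NULL)
  as.character(atom_selection)
}

# Per-MODEL structural validation of a PDB file.  bio3d does the coordinate
# parsing; this pre-scan guarantees the per-frame atom-count/ordering
# invariant holds and reports a structured error naming the offending frame
# before bio3d's multi-model reshape could fail opaquely.
validate_pdb_models <- function(lines, keep_names) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    groups <- list(which(is_atom))
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      abort("unbalanced MODEL/ENDMDL records.")
    }
    groups <- Map(function(s, e) {
      idx <- seq(s, e)
      idx[is_atom[idx]]
    }, model_starts, model_ends)
  }
  names_of <- function(idx) {
    ln <- lines[idx]
    name <- trimws(substr(ln, 13L, 16L))
    alt <- substr(ln, 17L, 17L)
    keep <- alt %in% c(" ", "", "A")
    name <- name[keep]
    if (!is.null(keep_names)) name <- name[name %in% keep_names]
    name
  }
  per_model <- lapply(groups, names_of)
  ref <- per_model[[1L]]
  if (length(ref) == 0L) abort("empty atom selection: no atoms match.")
  for (i in seq_along(per_model)) {
    cur <- per_model[[i]]
    if (length(cur) != length(ref)) {
      abort(sprintf("frame %d: expected %d atoms, found %d",
                    i, length(ref), length(cur)))
    }
    if (!identical(cur, ref)) {
      abort(sprintf("frame %d: atom ordering differs from frame 1", i))
    }
  }
  length(per_model)
}

read_frames_pdb <- function(path, atom_selection) {
  keep_names <- selection_names(atom_selection)
  lines <- readr::read_lines(path)
  n_models <- validate_pdb_models(lines, keep_names)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep <- atom$alt %in% c("A") | is.na(atom$alt) | atom$alt == ""
  if (!is.null(keep_names)) keep <- keep & trimws(atom$elety) %in% keep_names
  sel_atoms <- which(keep)
  if (length(sel_atoms) == 0L) abort("empty atom selection: no atoms match.")
  xyz_cols <- as.vector(rbind(3L * sel_atoms - 2L, 3L * sel_atoms - 1L, 3L * sel_atoms))
  values <- pdb$xyz[, xyz_cols, drop = FALSE]
  if (nrow(values) != n_models) {
    abort(sprintf("parsed %d coordinate frames but found %d MODEL blocks.",
                  nrow(values), n_models))
  }
  labels <- tibble::tibble(residue = as.integer(atom$resno[sel_atoms]),
                           atom = trimws(atom$elety[sel_atoms]))
  frame_matrix(values, atom_labels = labels)
}

read_frames_xyz <- function(path, atom_selection) {
  keep_names <- selection_names(atom_selection)
  lines <- readr::read_lines(path)
  pos <- 1L
  frames <- list()
  names_ref <- NULL
  frame_no <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[[pos]]))) {
    n_at <- suppressWarnings(as.integer(trimws(lines[[pos]])))
    if (is.na(n_at) || n_at < 1L) {
      abort(sprintf("xyz: invalid atom count at line %d.", pos))
    }
    if (pos + 1L + n_at > length(lines)) {
      abort(sprintf("xyz: truncated block starting at line %d.", pos))
    }
    frame_no <- frame_no + 1L
    body <- lines[(pos + 2L):(pos + 1L + n_at)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    nm <- vapply(toks, `[[`, character(1L), 1L)
    xyz <- vapply(toks, function(t) {
      if (length(t) < 4L) abort(sprintf("xyz: malformed atom line in frame %d.", frame_no))
      v <- suppressWarnings(as.numeric(t[2:4]))
      if (anyNA(v)) abort(sprintf("xyz: non-numeric coordinate in frame %d.", frame_no))
      v
    }, numeric(3L))
    keep <- if (is.null(keep_names)) rep(TRUE, n_at) else nm %in% keep_names
    if (!any(keep)) abort("empty atom selection: no atoms match.")
    nm <- nm[keep]
    row <- as.vector(xyz[, keep, drop = FALSE])
    if (is.null(names_ref)) {
      names_ref <- nm
    } else if (length(nm) != length(names_ref)) {
      abort(sprintf("frame %d: expected %d atoms, found %d",
                    frame_no, length(names_ref), length(nm)))
    } else if (!identical(nm, names_ref)) {
      abort(sprintf("frame %d: atom ordering differs from frame 1", frame_no))
    }
    frames[[frame_no]] <- row
    pos <- pos + 2L + n_at
    while (pos <= length(lines) && !nzchar(trimws(lines[[pos]]))) pos <- pos + 1L
  }
  if (frame_no == 0L) abort("xyz: no frames found.")
  values <- do.call(rbind, frames)
  labels <- tibble::tibble(residue = seq_along(names_ref), atom = names_ref)
  frame_matrix(values, atom_labels = labels)
}

read_frames_matrix <- function(path, atom_selection) {
  if (!identical(atom_selection, "all")) {
    abort("the matrix format carries no atom names; use atom_selection = \"all\".")
  }
  first <- readr::read_lines(path, n_max = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
         if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE, colClasses = "numeric",
                      strip.white = TRUE),
    error = function(e) abort(sprintf("non-numeric coordinate in matrix file: %s",
                                      conditionMessage(e)))
  )
  frame_matrix(as.matrix(df))
}

#' Write a frame matrix to the delimited interchange format
#'
#' One frame per row, comma-separated, full double precision (`%.17g`) so a
#' write/read round trip reproduces the coordinates bit-exactly.
#'
#' @param frames An `ecs_frames` object (or anything [as_frame_matrix()]
#'   accepts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames_matrix <- function(frames, path) {
  frames <- as_frame_matrix(frames)
  v <- frames$values
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, path)
  invisible(path)
}

#' Write a frame matrix as an XYZ trajectory
#'
#' Repeated blocks of atom count, a comment line carrying the frame id, and
#' `name x y z` atom lines.
#'
#' @inheritParams write_frames_matrix
#' @return `path`, invisibly.
#' @export
write_frames_xyz <- function(frames, path) {
  frames <- as_frame_matrix(frames)
  v <- frames$values
  nm <- frames$atom_labels$atom
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(v))) {
    coords <- matrix(v[i, ], nrow = 3L)
    writeLines(c(
      as.character(frames$n_atoms),
      sprintf("frame %d", frames$frame_ids[[i]]),
      sprintf("%s %.17g %.17g %.17g", nm, coords[1L, ], coords[2L, ], coords[3L, ])
    ), con)
  }
  invisible(path)
}

#' Write a diversity selection to a TSV report
#'
#' Columns: `rank` (1-based selection order), `frame` (frame id) and
#' `similarity` (the extended similarity of the selected set at the step the
#' frame was added; `NA` for the medoid, which has no prior set).  Byte
#' output is deterministic for a fixed selection.
#'
#' @param result An `ecs_selection` from [ecs_mediv_select()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  if (!inherits(result, "ecs_selection")) {
    abort("`result` must be an `ecs_selection` object.")
  }
  if (length(result$order) == 0L) abort("empty selection: nothing to write.")
  tb <- tidy(result)
  sim <- ifelse(is.na(tb$similarity), "NA", sprintf("%.12g", tb$similarity))
  lines <- c("rank\tframe\tsimilarity",
             sprintf("%d\t%d\t%s", tb$rank, tb$frame, sim))
  writeLines(lines, path)
  invisible(path)
}

#' Read a selection TSV written by [write_selection()]
#'
#' @param path Path to a selection TSV.
#' @return A tibble with columns `rank`, `frame`, `similarity`.
#' @export
read_selection <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(),
    frame = readr::col_integer(),
    similarity = readr::col_double()
  ))
}
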