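#' Simulate a multi-basin trajectory
#'
#' Generates a synthetic trajectory whose frames visit `k_basins` distinct
#' conformational states: basin centres are drawn uniformly in a cube of
#' edge `basin_spread` (in the full \eqn{m}-dimensional coordinate space),
#' frames are assigned to basins in contiguous blocks — mimicking the dwell
#' periods an MD trajectory spends in a metastable state, with the block
#' order a seeded permutation — and each frame is its basin centre plus
#' isotropic Gaussian noise.  Everything is reproducible from `seed`.
#'
#' The defaults emulate the regime of the trajectory case studies this
#' package targets: 1000 frames per trajectory, backbone-scale atom counts,
#' basin separations an order of magnitude above the thermal noise.
#'
#' @param n_frames Number of frames.  Default 1000.
#' @param n_atoms Atoms per frame (3 coordinates each).  Default 30.
#' @param k_basins Number of conformational basins.  Default 3.
#' @param basin_spread Edge (Angstrom) of the cube the basin centres are
#'   drawn from; controls between-basin separation.  Default 20.
#' @param noise_sd Isotropic within-basin noise standard deviation
#'   (Angstrom).  Default 1.
#' @param seed Integer seed.
#' @return An `ecs_traj` object: `frames` (`ecs_frames`), `basin_labels`
#'   (integer in `1:k_basins` per frame), `centers` (k x m matrix) and
#'   `params`.
#' @examples
#' traj <- make_multibasin(n_frames = 30, n_atoms = 4, k_basins = 2, seed = 1)
#' table(traj$basin_labels)
#' @export
make_multibasin <- function(n_frames = 1000L, n_atoms = 30L, k_basins = 3L,
                            basin_spread = 20, noise_sd = 1, seed = 1L) {
  if (k_basins < 1L) abort("`k_basins` must be >= 1.")
  if (basin_spread <= 0) abort("`basin_spread` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_frames < k_basins) abort("need at least one frame per basin.")
  m <- 3L * n_atoms
  out <- withr::with_seed(as.integer(seed), {
    centers <- matrix(runif(k_basins * m, 0, basin_spread), nrow = k_basins)
    block_order <- sample.int(k_basins)
    bounds <- round(seq(0L, n_frames, length.out = k_basins + 1L))
    labels <- integer(n_frames)
    for (b in seq_len(k_basins)) {
      labels[(bounds[b] + 1L):bounds[b + 1L]] <- block_order[[b]]
    }
    values <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n_frames * m, 0, noise_sd), nrow = n_frames)
    list(centers = centers, labels = labels, values = values)
  })
  new_ecs_traj(
    frames = frame_matrix(out$values),
    basin_labels = out$labels,
    centers = out$centers,
    params = list(mode = "multibasin", n_frames = n_frames, n_atoms = n_atoms,
                  k_basins = k_basins, basin_spread = basin_spread,
                  noise_sd = noise_sd, seed = as.integer(seed))
  )
}

#' Simulate a drifting (random-walk) trajectory
#'
#' Gaussian random walk of the full coordinate vector, emulating a linearly
#' progressing trajectory that explores conformational space sparsely and
#' never revisits a state.  Labels split the frames into four equal
#' time-quantile segments.
#'
#' @param n_frames Number of frames.  Default 1000.
#' @param n_atoms Atoms per frame.  Default 30.
#' @param step_sd Per-coordinate step standard deviation (Angstrom) between
#'   consecutive frames.  Default 0.5.
#' @param seed Integer seed.
#' @return An `ecs_traj` object; `centers` holds the walk start (all zeros).
#' @export
make_drift <- function(n_frames = 1000L, n_atoms = 30L, step_sd = 0.5,
                       seed = 1L) {
  if (step_sd <= 0) abort("`step_sd` must be > 0.")
  if (n_frames < 2L) abort("need at least 2 frames.")
  m <- 3L * n_atoms
  values <- withr::with_seed(as.integer(seed), {
    steps <- matrix(rnorm((n_frames - 1L) * m, 0, step_sd), nrow = n_frames - 1L)
    rbind(0, apply(steps, 2L, cumsum))
  })
  labels <- as.integer(ceiling(4 * seq_len(n_frames) / n_frames))
  new_ecs_traj(
    frames = frame_matrix(values),
    basin_labels = labels,
    centers = matrix(0, nrow = 1L, ncol = m),
    params = list(mode = "drift", n_frames = n_frames, n_atoms = n_atoms,
                  step_sd = step_sd, seed = as.integer(seed))
  )
}

new_ecs_traj <- function(frames, basin_labels, centers, params) {
  structure(
    list(frames = frames, basin_labels = as.integer(basin_labels),
         centers = centers, params = params),
    class = "ecs_traj"
  )
}

#' @export
print.ecs_traj <- function(x, ...) {
  p <- x$params
  cat(sprintf("<ecs_traj> %s: %d frames x %d atoms (seed %d)\n",
              p$mode, p$n_frames, p$n_atoms, p$seed))
  invisible(x)
}

#' Write a synthetic trajectory to fixture files
#'
#' Coordinates go to the delimited matrix format (or XYZ), basin labels to
#' a sidecar TSV with columns `frame` and `basin`.
#'
#' @param traj An `ecs_traj` object.
#' @param path Coordinate file path.
#' @param format `"matrix"` (default) or `"xyz"`.
#' @param labels_path Optional path for the label sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("matrix", "xyz"),
                             labels_path = NULL) {
  stopifnot(inherits(traj, "ecs_traj"))
  format <- match.arg(format)
  switch(format,
         matrix = write_frames_matrix(traj$frames, path),
         xyz = write_frames_xyz(traj$frames, path))
  if (!is.null(labels_path)) {
    readr::write_tsv(
      tibble::tibble(frame = traj$frames$frame_ids, basin = traj$basin_labels),
      labels_path
    )
  }
  invisible(path)
}

#' Plot a trajectory in its first two principal components
#'
#' A quick look at the conformational landscape of a (synthetic or real)
#' trajectory: frames projected on the first two principal components of
#' the coordinate matrix, coloured by basin label when available, with
#' selected frames highlighted when a selection is supplied.
#'
#' @param object An `ecs_traj` object.
#' @param selection Optional `ecs_selection` to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecs_traj
#' @export
autoplot.ecs_traj <- function(object, selection = NULL, ...) {
  pc <- prcomp(object$frames$values, rank. = 2L)
  tb <- tibble::tibble(PC1 = pc$x[, 1L], PC2 = pc$x[, 2L],
                       basin = factor(object$basin_labels))
  gg <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = .data$basin)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(title = "Trajectory in PC space") +
    ggplot2::theme_minimal()
  if (!is.null(selection)) {
    sel_tb <- tb[selection$order, ]
    gg <- gg + ggplot2::geom_point(data = sel_tb, colour = "black",
                                   shape = 4, size = 3, stroke = 1.2)
  }
  gg
}
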