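#' Pairwise RMSD between two frames
#'
#' \eqn{\mathrm{RMSD}(a,b) = \sqrt{\frac{1}{n_{atoms}} \sum_k \lVert r_a^{(k)}
#' - r_b^{(k)} \rVert^2}} on raw (unnormalized) coordinates.  Frames are
#' assumed pre-aligned, as is the case for coordinates extracted from a
#' single simulation; no superposition is applied by default.  With
#' `superpose = TRUE` the second frame is first fitted onto the first by
#' optimal rigid-body superposition (Kabsch, via bio3d), which can only
#' lower the value.
#'
#' @param frame_a,frame_b Numeric coordinate rows of equal length (flattened
#'   x,y,z; length divisible by 3), in Angstrom.
#' @param superpose Rigid-body fit `frame_b` onto `frame_a` first.  Default
#'   `FALSE`.
#' @return The RMSD in Angstrom.
#' @examples
#' pair_rmsd(c(0, 0, 0), c(3, 4, 0))  # 5 (3-4-5 triangle)
#' @export
pair_rmsd <- function(frame_a, frame_b, superpose = FALSE) {
  if (length(frame_a) != length(frame_b)) {
    abort("frames have mismatched coordinate lengths.")
  }
  if (length(frame_a) %% 3L != 0L) abort("coordinate length must be divisible by 3.")
  if (superpose) {
    inds <- seq_along(frame_a)
    frame_b <- as.numeric(bio3d::fit.xyz(fixed = frame_a, mobile = frame_b,
                                         fixed.inds = inds,
                                         mobile.inds = inds))
  }
  n_atoms <- length(frame_a) %/% 3L
  sqrt(sum((frame_a - frame_b)^2) / n_atoms)
}

#' Average pairwise RMSD of a selection
#'
#' The diversity figure of merit for a selected frame set: the mean RMSD
#' over all unordered pairs of selected frames (larger is more diverse),
#' with a spread measure defined as the root-mean-square of the deviations
#' of the individual pair RMSDs from that mean (population form, dividing
#' by the number of pairs).
#'
#' @param frames Frames (`ecs_frames`, matrix, data frame or `ecs_traj`)
#'   holding raw coordinates.
#' @param order Indices of the selected frames (no duplicates), e.g.
#'   `ecs_mediv_select(...)$order`.
#' @param superpose Rigid-body fit each pair before the RMSD.  Default
#'   `FALSE`.
#' @return An `ecs_eval` object with `avg_rmsd`, `std_rmsd`, `n_pairs` and
#'   the full `pairwise` tibble (`frame_i`, `frame_j`, `rmsd`).  [glance()]
#'   gives the one-row summary, [tidy()] the pair list.
#' @examples
#' fm <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
#' glance(selection_rmsd_stats(fm, 1:3))
#' @export
selection_rmsd_stats <- function(frames, order, superpose = FALSE) {
  frames <- as_frame_matrix(frames)
  order <- as.integer(order)
  if (length(order) < 2L) abort("need at least 2 selected frames.")
  if (anyDuplicated(order)) abort("duplicate frame indices in selection.")
  if (any(order < 1L | order > nrow(frames$values))) {
    abort("selection indices out of range.")
  }
  sub <- frames$values[order, , drop = FALSE]
  n_atoms <- frames$n_atoms
  k <- length(order)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  if (superpose) {
    rmsd <- apply(pairs, 1L, function(ij) {
      pair_rmsd(sub[ij[[1L]], ], sub[ij[[2L]], ], superpose = TRUE)
    })
  } else {
    rmsd <- as.vector(dist(sub)) / sqrt(n_atoms)
    # dist() enumerates pairs column-major (1-2, 1-3, 2-3, ...): reorder to
    # match the upper-triangle row/col enumeration used for the pair labels.
    dd <- matrix(0, k, k)
    dd[lower.tri(dd)] <- rmsd
    rmsd <- dd[cbind(pairs[, 2L], pairs[, 1L])]
  }
  avg <- mean(rmsd)
  std <- sqrt(mean((rmsd - avg)^2))
  structure(
    list(avg_rmsd = avg, std_rmsd = std, n_pairs = length(rmsd),
         pairwise = tibble::tibble(frame_i = order[pairs[, 1L]],
                                   frame_j = order[pairs[, 2L]],
                                   rmsd = rmsd),
         superpose = superpose),
    class = "ecs_eval"
  )
}

#' @export
print.ecs_eval <- function(x, ...) {
  cat(sprintf("<ecs_eval> avg pairwise RMSD %.4f A (std %.4f, %d pairs%s)\n",
              x$avg_rmsd, x$std_rmsd, x$n_pairs,
              if (x$superpose) ", superposed" else ""))
  invisible(x)
}

#' @method tidy ecs_eval
#' @export
tidy.ecs_eval <- function(x, ...) x$pairwise

#' @method glance ecs_eval
#' @export
glance.ecs_eval <- function(x, ...) {
  tibble::tibble(avg_rmsd = x$avg_rmsd, std_rmsd = x$std_rmsd,
                 n_pairs = x$n_pairs)
}

#' Rank selection methods by their RMSD diversity scores
#'
#' Given a table of average pairwise RMSD values (rows = methods, columns =
#' cases, e.g. different selection sizes or systems), ranks the methods
#' within each case with rank 1 for the *highest* RMSD (more diverse is
#' better).  Ties receive average ranks; a case with a tie at the top gives
#' every tied method a win.
#'
#' @param rmsd_table Numeric matrix or data frame, methods in rows (row
#'   names = method labels), cases in columns.  No missing cells.
#' @return A tibble with columns `method`, `wins`, `rank_sum`, sorted by
#'   decreasing wins then increasing rank sum.
#' @examples
#' m <- rbind(a = c(1, 2), b = c(2, 1))
#' rank_methods(m)
#' @export
rank_methods <- function(rmsd_table) {
  if (is.data.frame(rmsd_table)) {
    nm <- if (!is.null(rmsd_table$method)) rmsd_table$method else rownames(rmsd_table)
    rmsd_table <- as.matrix(rmsd_table[setdiff(names(rmsd_table), "method")])
    rownames(rmsd_table) <- nm
  }
  if (!is.numeric(rmsd_table) || anyNA(rmsd_table)) {
    abort("`rmsd_table` must be a complete numeric methods x cases table.")
  }
  if (is.null(rownames(rmsd_table))) {
    rownames(rmsd_table) <- paste0("method", seq_len(nrow(rmsd_table)))
  }
  ranks <- apply(rmsd_table, 2L, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(rmsd_table))
  wins <- apply(rmsd_table, 2L, function(col) col == max(col))
  tibble::tibble(
    method = rownames(rmsd_table),
    wins = as.integer(rowSums(matrix(wins, nrow = nrow(rmsd_table)))),
    rank_sum = rowSums(ranks)
  ) |>
    dplyr::arrange(dplyr::desc(.data$wins), .data$rank_sum)
}

#' Random-selection diversity baseline
#'
#' Draws `n_draws` uniform `k`-subsets of the frames (without replacement,
#' seeded) and reports the average pairwise RMSD of each — the null
#' distribution against which a diversity picker can be judged.
#'
#' @param frames Frames holding raw coordinates.
#' @param k Subset size, between 2 and \eqn{N}.
#' @param n_draws Number of random subsets.  Default 1000.
#' @param seed Integer seed; draws are fully reproducible.
#' @param superpose Passed to [selection_rmsd_stats()].
#' @return A tibble with columns `draw` and `avg_rmsd`.
#' @export
random_selection_baseline <- function(frames, k, n_draws = 1000L, seed = 1L,
                                      superpose = FALSE) {
  frames <- as_frame_matrix(frames)
  n <- nrow(frames$values)
  if (k < 2L || k > n) abort("`k` must be between 2 and the number of frames.")
  draws <- withr::with_seed(seed, {
    replicate(n_draws, sample.int(n, k), simplify = FALSE)
  })
  avg <- vapply(draws, function(ix) {
    selection_rmsd_stats(frames, ix, superpose = superpose)$avg_rmsd
  }, numeric(1L))
  tibble::tibble(draw = seq_len(n_draws), avg_rmsd = avg)
}

#' Compare a selection against the random baseline, graphically
#'
#' Histogram of the baseline average-RMSD distribution with the picker's
#' value marked.
#'
#' @param baseline Tibble from [random_selection_baseline()].
#' @param selection_avg_rmsd The picker's average pairwise RMSD.
#' @return A ggplot object.
#' @export
plot_baseline_comparison <- function(baseline, selection_avg_rmsd) {
  ggplot2::ggplot(baseline, ggplot2::aes(x = .data$avg_rmsd)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = selection_avg_rmsd,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "average pairwise RMSD (A)", y = "random draws",
                  title = "Selection diversity vs. random baseline") +
    ggplot2::theme_minimal()
}
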