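#' Complementary similarity of every frame
#'
#' For each frame \eqn{i}, the extended similarity of the set with frame
#' \eqn{i} removed (object count \eqn{N-1}).  Removing a central frame
#' leaves the set's outliers exposed, so central frames score *low*;
#' removing an outlier tightens the set, so outliers score high.  The
#' leave-one-out column sums are obtained by subtracting each row from the
#' total column-sum vector — one pass over the matrix, \eqn{O(Nm)} overall —
#' rather than recomputing each subset from scratch.
#'
#' @param norm An `ecs_norm` object (or frames, normalized on the fly).
#' @param index Index name; case-insensitive.
#' @param gamma Coincidence threshold, default 0.
#' @param weighted Weighted counters, default `FALSE`.
#' @return Numeric vector of length \eqn{N}: entry \eqn{i} is the extended
#'   similarity of all frames except \eqn{i}.
#' @export
complementary_similarities <- function(norm, index = "RT", gamma = 0,
                                       weighted = FALSE) {
  norm <- as_norm(norm)
  index <- match_index(index)
  v <- norm$values
  n <- nrow(v)
  if (n < 3L) abort("complementary similarity needs at least 3 frames.")
  loo_sums <- sweep(-v, 2L, colSums(v), "+")
  index_over_sums(loo_sums, n - 1L, index, gamma, weighted)
}

#' Medoid of a conformation set
#'
#' The most representative frame: the one whose removal leaves the lowest
#' extended similarity among the rest, i.e. the argmin of
#' [complementary_similarities()].  Ties resolve to the lowest frame index.
#'
#' @inheritParams complementary_similarities
#' @return The medoid's row index (1-based).
#' @export
find_medoid <- function(norm, index = "RT", gamma = 0, weighted = FALSE) {
  which.min(complementary_similarities(norm, index, gamma, weighted))
}

#' ECS-MeDiv diversity selection
#'
#' Selects `n_select` maximally diverse yet representative frames.  The
#' picker starts from the medoid (so the sample is anchored at the most
#' central conformation, not at an arbitrary outlier) and then grows the
#' set greedily: at each step the candidate whose addition gives the
#' *lowest* extended similarity of the enlarged set is appended.  Candidates
#' whose similarity lies within `tie_tol` of the minimum are tied; the tie
#' is resolved by the lowest mean pairwise similarity (same index, two-object
#' form under the global scaling) to the already-selected frames, and any
#' remaining tie by the lowest frame index.  The growing-set similarities are
#' evaluated from a running column-sum vector of the selected rows, so each
#' step costs \eqn{O(Nm)} and the whole selection scales linearly in the
#' number of frames for a fixed (small) `n_select`.
#'
#' @param x Frames (`ecs_frames`, matrix, data frame, or `ecs_traj`) or an
#'   `ecs_norm`.  Normalization, when needed, uses the global min/max of the
#'   full input.
#' @param n_select Number of frames to select, between 1 and \eqn{N}.
#' @param index Index name; case-insensitive.  The trajectory studies behind
#'   this package favour `"RT"` (Rogers-Tanimoto) and `"CT2"`
#'   (Consonni-Todeschini 2).
#' @param gamma Coincidence threshold, default 0.
#' @param weighted Weighted counters, default `FALSE`.
#' @param tie_tol Absolute tolerance within which candidate similarities are
#'   treated as tied.  Default `1e-12`.
#' @return An `ecs_selection` object with elements `order` (selected frame
#'   indices, medoid first), `step_similarity` (similarity of the first
#'   \eqn{k} selected frames at each step; `NA` for the medoid),
#'   `tiebreaks` (audit tibble: step, tied candidates, their mean pairwise
#'   similarities, the winner), `index`, `gamma`, `weighted`, `n_frames`.
#'   Use [tidy()] / [glance()] / [autoplot()] on it, or [write_selection()].
#' @examples
#' traj <- make_multibasin(n_frames = 60, n_atoms = 5, k_basins = 3, seed = 7)
#' sel <- ecs_mediv_select(traj, n_select = 3, index = "RT")
#' tidy(sel)
#' @export
ecs_mediv_select <- function(x, n_select, index = "RT", gamma = 0,
                             weighted = FALSE, tie_tol = 1e-12) {
  norm <- as_norm(x)
  index <- match_index(index)
  v <- norm$values
  n <- nrow(v)
  if (n_select < 1L || n_select > n) {
    abort(sprintf("`n_select` must be between 1 and the number of frames (%d).", n))
  }
  n_select <- as.integer(n_select)
  if (n == 2L) {
    # Degenerate pool: no medoid is defined, both frames in index order.
    order <- seq_len(min(n_select, 2L))
    step_sim <- c(NA_real_,
                  if (n_select >= 2L) similarity_of_set(norm, index, gamma, weighted))
    return(new_ecs_selection(order, step_sim[seq_along(order)],
                             empty_tiebreaks(), index, gamma, weighted, n))
  }
  order <- integer(n_select)
  step_sim <- rep(NA_real_, n_select)
  order[1L] <- find_medoid(norm, index, gamma, weighted)
  audits <- list()
  selected_sum <- v[order[1L], ]
  in_set <- logical(n)
  in_set[order[1L]] <- TRUE
  for (step in seq_len(n_select)[-1L]) {
    cand <- which(!in_set)
    cand_sums <- sweep(v[cand, , drop = FALSE], 2L, selected_sum, "+")
    vals <- index_over_sums(cand_sums, step, index, gamma, weighted)
    mn <- min(vals)
    tied <- which(vals <= mn + tie_tol)
    if (length(tied) > 1L) {
      sel_rows <- v[order[seq_len(step - 1L)], , drop = FALSE]
      mean_pair <- vapply(tied, function(t) {
        pair_sums <- sweep(sel_rows, 2L, v[cand[t], ], "+")
        kp <- counters_kernel(pair_sums, 2L, gamma)
        mean(index_kernel(kp, index, weighted = weighted))
      }, numeric(1L))
      winner <- tied[which.min(mean_pair)]
      audits[[length(audits) + 1L]] <- tibble::tibble(
        step = step,
        candidate = cand[tied],
        similarity = vals[tied],
        mean_pairwise = mean_pair,
        chosen = cand[tied] == cand[winner]
      )
    } else {
      winner <- tied[[1L]]
    }
    pick <- cand[winner]
    order[step] <- pick
    step_sim[step] <- vals[winner]
    selected_sum <- selected_sum + v[pick, ]
    in_set[pick] <- TRUE
  }
  tiebreaks <- if (length(audits)) dplyr::bind_rows(audits) else empty_tiebreaks()
  new_ecs_selection(order, step_sim, tiebreaks, index, gamma, weighted, n)
}

empty_tiebreaks <- function() {
  tibble::tibble(step = integer(), candidate = integer(),
                 similarity = double(), mean_pairwise = double(),
                 chosen = logical())
}

new_ecs_selection <- function(order, step_similarity, tiebreaks, index,
                              gamma, weighted, n_frames) {
  structure(
    list(order = as.integer(order), step_similarity = step_similarity,
         tiebreaks = tiebreaks, index = index, gamma = gamma,
         weighted = weighted, n_frames = as.integer(n_frames)),
    class = "ecs_selection"
  )
}

#' @export
print.ecs_selection <- function(x, ...) {
  cat(sprintf("<ecs_selection> %d of %d frames, index %s%s\n",
              length(x$order), x$n_frames, x$index,
              if (x$weighted) " (weighted)" else ""))
  cat("order:", paste(x$order, collapse = " "), "\n")
  if (nrow(x$tiebreaks)) {
    cat(sprintf("tiebreaks invoked at %d step(s)\n",
                length(unique(x$tiebreaks$step))))
  }
  invisible(x)
}

#' Tidy an ECS-MeDiv selection
#'
#' @param x An `ecs_selection`.
#' @param ... Unused.
#' @return A tibble with one row per selected frame: `rank` (selection
#'   order, 1-based), `frame` (frame index) and `similarity` (extended
#'   similarity of the selected set when the frame was added; `NA` for the
#'   medoid).
#' @method tidy ecs_selection
#' @export
tidy.ecs_selection <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$order), frame = x$order,
                 similarity = x$step_similarity)
}

#' One-row summary of an ECS-MeDiv selection
#'
#' @param x An `ecs_selection`.
#' @param ... Unused.
#' @return A tibble with columns `n_selected`, `n_frames`, `index`,
#'   `medoid`, `final_similarity`, `n_tiebreak_steps`.
#' @method glance ecs_selection
#' @export
glance.ecs_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$order),
    n_frames = x$n_frames,
    index = x$index,
    medoid = x$order[[1L]],
    final_similarity = x$step_similarity[[length(x$step_similarity)]],
    n_tiebreak_steps = length(unique(x$tiebreaks$step))
  )
}

#' Plot the similarity trace of a selection
#'
#' Extended similarity of the growing selected set at each pick.  A steep
#' fall then plateau is typical: early picks jump between distant basins,
#' later picks refine within them.
#'
#' @param object An `ecs_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecs_selection
#' @export
autoplot.ecs_selection <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb[-1L, ], ggplot2::aes(x = .data$rank, y = .data$similarity)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = tb$rank) +
    ggplot2::labs(
      x = "selection step",
      y = sprintf("extended %s similarity of selected set", object$index),
      title = sprintf("ECS-MeDiv similarity trace (%d of %d frames)",
                      length(object$order), object$n_frames)
    ) +
    ggplot2::theme_minimal()
}
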