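#' The sixteen extended continuous similarity indices
#'
#' Returns the canonical short names of the supported indices.  Names are
#' accepted case-insensitively wherever an `index` argument appears, and
#' `"all"` expands to the full set.  The indices generalise classical binary
#' association coefficients (Jaccard-Tanimoto, Rogers-Tanimoto,
#' Sokal-Michener, Consonni-Todeschini, ...) to an arbitrary number of
#' real-valued vectors.
#'
#' @return Character vector of length 16.
#' @export
ecs_indices <- function() {
  c("AC", "BUB", "CT1", "CT2", "CT3", "CT4", "Fai", "Gle",
    "Ja", "Ja0", "JT", "RR", "RT", "SM", "SS1", "SS2")
}

match_index <- function(index, several.ok = FALSE) {
  idx <- ecs_indices()
  if (length(index) == 1L && tolower(index) == "all") {
    if (!several.ok) abort("a single index name is required here.")
    return(idx)
  }
  pos <- match(tolower(index), tolower(idx))
  if (anyNA(pos)) {
    abort(sprintf("unknown similarity index: %s (see ecs_indices()).",
                  paste(index[is.na(pos)], collapse = ", ")))
  }
  if (!several.ok && length(pos) != 1L) abort("a single index name is required here.")
  idx[pos]
}

#' Min-max normalize a frame matrix
#'
#' Rescales all coordinates to \eqn{[0,1]} with a single global pair of
#' extrema, \eqn{n(q) = (q - \min q) / (\max q - \min q)}, the minimum and
#' maximum taken over *every* entry of the matrix.  A single uniform affine
#' scaling is the only choice consistent with RMSD-based assessment: it
#' multiplies all L1 distances between frames by the same positive constant,
#' so the relative ordering of conformations is untouched.  A constant
#' matrix (max equals min) maps to all zeros.
#'
#' The similarity machinery is fully general: any numeric matrix of
#' real-valued object vectors is accepted, not only 3-per-atom coordinate
#' blocks (the indices apply to arbitrary continuous data).
#'
#' @param frames An `ecs_frames` object, `ecs_traj`, or any numeric matrix /
#'   data frame with objects in rows.
#' @return An `ecs_norm` object: `values` in \eqn{[0,1]}, `global_min`,
#'   `global_max`, `n_frames`, plus the originating `frame_ids`.
#' @examples
#' normalize_frames(rbind(c(0, 2, 0), c(4, 2, 0), c(1, 1, 0)))
#' @export
normalize_frames <- function(frames) {
  frames <- as_value_matrix(frames)
  v <- frames$values
  gmin <- min(v)
  gmax <- max(v)
  values <- if (gmax > gmin) (v - gmin) / (gmax - gmin) else array(0, dim(v))
  structure(
    list(values = values, global_min = gmin, global_max = gmax,
         n_frames = nrow(v), frame_ids = frames$frame_ids,
         n_atoms = frames$n_atoms),
    class = "ecs_norm"
  )
}

# Relaxed coercion for the similarity machinery: coordinate containers pass
# through frame_matrix validation, plain matrices only need to be numeric
# and finite (no 3-per-atom constraint).
as_value_matrix <- function(x) {
  if (inherits(x, "ecs_traj")) x <- x$frames
  if (inherits(x, "ecs_frames")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("input must be a numeric matrix, data frame, ecs_frames or ecs_traj.")
  }
  if (!all(is.finite(x))) abort("non-finite values in input matrix.")
  dimnames(x) <- NULL
  list(values = x, frame_ids = seq_len(nrow(x)),
       n_atoms = if (ncol(x) %% 3L == 0L) ncol(x) %/% 3L else NA_integer_)
}

#' @export
print.ecs_norm <- function(x, ...) {
  cat(sprintf("<ecs_norm> %d frames x %d columns, global range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$global_min, x$global_max))
  invisible(x)
}

as_norm <- function(x) {
  if (inherits(x, "ecs_norm")) return(x)
  normalize_frames(x)
}

#' Column sums of a normalized matrix
#'
#' The column-sum vector of the normalized conformation matrix, together with
#' the object count \eqn{N}, is the sole input every extended similarity
#' index needs: the whole set is condensed into \eqn{m} numbers in one linear
#' pass.
#'
#' @param norm An `ecs_norm` object (or frames, normalized on the fly).
#' @return An `ecs_colsums` object with elements `sums` (length \eqn{m}, each
#'   in \eqn{[0, N]}) and `n_objects`.
#' @export
column_sums <- function(norm) {
  norm <- as_norm(norm)
  structure(
    list(sums = colSums(norm$values), n_objects = nrow(norm$values)),
    class = "ecs_colsums"
  )
}

# Vectorised counter classification.  `sums` may be a vector (one set) or a
# matrix whose rows are independent column-sum vectors sharing `n`.
# Columns with |2s - n| > gamma carry a similarity signal (1-similarity when
# s > n/2, 0-similarity when s < n/2); the rest are dissimilarity columns.
# Each column enters the raw counters (a, d, bc) with count 1 and the
# weighted counters (w_a, w_d, w_bc) with the fraction weights
# f_s(delta) = delta/n for similarity columns and
# f_d(delta) = 1 - (delta - n mod 2)/n for dissimilarity columns.
# In the binary two-object limit (gamma = 0) every weight is exactly 1, so
# raw and weighted counters coincide and the classical coefficients are
# recovered.
counters_kernel <- function(sums, n, gamma = 0) {
  if (!is.matrix(sums)) sums <- matrix(sums, nrow = 1L)
  delta <- abs(2 * sums - n)
  sim <- delta > gamma
  hi <- sums > n / 2
  is_a <- sim & hi
  is_d <- sim & !hi
  w_sim <- delta / n
  w_dis <- 1 - (delta - n %% 2L) / n
  a <- rowSums(is_a)
  d <- rowSums(is_d)
  bc <- rowSums(!sim)
  w_a <- rowSums(is_a * w_sim)
  w_d <- rowSums(is_d * w_sim)
  w_bc <- rowSums((!sim) * w_dis)
  list(a = a, d = d, bc = bc, p = a + d + bc,
       w_a = w_a, w_d = w_d, w_bc = w_bc, w_p = w_a + w_d + w_bc)
}

#' Classify column sums into similarity counters
#'
#' Each column \eqn{j} of the column-sum vector is scored by
#' \eqn{\Delta_j = |2 s_j - N|}.  Columns with \eqn{\Delta_j > \gamma} agree
#' strongly across the set: they feed the 1-similarity counter `a` when
#' \eqn{s_j > N/2} (coordinates concentrated near 1) or the 0-similarity
#' counter `d` when \eqn{s_j < N/2}.  The remaining columns carry no
#' consensus and feed the dissimilarity counter `bc`.  Every column
#' contributes a count of 1 to the raw counters — so `a + d + bc = p = m`
#' always — and, in parallel, a weight to the weighted counters:
#' \eqn{f_s(\Delta_j) = \Delta_j/N} for similarity columns (unanimous
#' columns weigh 1, borderline columns almost 0) and
#' \eqn{f_d(\Delta_j) = 1 - (\Delta_j - N \bmod 2)/N} for dissimilarity
#' columns.  The weighting is what lets the indices discriminate on
#' continuous coordinates, where essentially every column clears a zero
#' threshold; in the two-object binary limit every weight is exactly 1 and
#' the raw and weighted counters coincide.
#'
#' @param cs An `ecs_colsums` object from [column_sums()].
#' @param gamma Coincidence threshold \eqn{\gamma \ge 0}; columns need
#'   \eqn{\Delta_j > \gamma} (strict) to count as similarity columns.
#'   Default 0.
#' @param weighted Marks the counter set for the fully weighted index
#'   family, in which the index denominators also use the weighted
#'   counters.  Default `FALSE` — the "nonweighted" family (weighted
#'   numerators over raw-count denominators), the variant used throughout
#'   trajectory work.
#' @return An `ecs_counters` object: raw `a`, `d`, `bc`, `p`; weighted
#'   `w_a`, `w_d`, `w_bc`, `w_p`; plus `gamma`, `weighted`, `n_objects`.
#' @export
classify_counters <- function(cs, gamma = 0, weighted = FALSE) {
  stopifnot(inherits(cs, "ecs_colsums"))
  n <- cs$n_objects
  if (n < 2L) abort("similarity undefined for fewer than two objects")
  if (gamma < 0 || gamma >= n) abort("`gamma` must satisfy 0 <= gamma < N.")
  k <- counters_kernel(cs$sums, n, gamma)
  structure(
    list(a = k$a[[1L]], d = k$d[[1L]], bc = k$bc[[1L]], p = k$p[[1L]],
         w_a = k$w_a[[1L]], w_d = k$w_d[[1L]], w_bc = k$w_bc[[1L]],
         w_p = k$w_p[[1L]],
         gamma = gamma, weighted = weighted, n_objects = n),
    class = "ecs_counters"
  )
}

#' @export
print.ecs_counters <- function(x, ...) {
  cat(sprintf("<ecs_counters> a=%g d=%g bc=%g p=%g | w_a=%g w_d=%g w_bc=%g (N=%d, gamma=%g, %s)\n",
              x$a, x$d, x$bc, x$p, x$w_a, x$w_d, x$w_bc, x$n_objects, x$gamma,
              if (x$weighted) "weighted" else "nonweighted"))
  invisible(x)
}

# Vectorised index evaluation from a counter list (as from counters_kernel).
# Numerators always use the weighted counters; denominators use the raw
# column counts in the default "nonweighted" family and the weighted
# counters in the fully weighted family.  0/0 forms are defined as 0 (no
# similarity evidence); `warn_zero` surfaces that as a warning in the
# scalar user-facing path.
index_kernel <- function(k, index, weighted = FALSE, warn_zero = FALSE) {
  na <- k$w_a; nd <- k$w_d; nbc <- k$w_bc
  if (weighted) {
    da <- k$w_a; dd <- k$w_d; dbc <- k$w_bc; dp <- k$w_p
  } else {
    da <- k$a; dd <- k$d; dbc <- k$bc; dp <- k$p
  }
  zero_div <- FALSE
  sdiv <- function(num, den) {
    z <- den == 0
    if (any(z)) {
      zero_div <<- TRUE
      den[z] <- 1
      num[z] <- 0
    }
    num / den
  }
  val <- switch(index,
    RR  = sdiv(na, dp),
    SM  = sdiv(na + nd, dp),
    JT  = sdiv(na, da + dbc),
    RT  = sdiv(na + nd, dp + dbc),
    CT1 = sdiv(log1p(na + nd), log1p(dp)),
    CT2 = sdiv(log1p(k$w_p) - log1p(nbc), log1p(dp)),
    CT3 = sdiv(log1p(na), log1p(dp)),
    CT4 = sdiv(log1p(na), log1p(da + dbc)),
    Fai = sdiv(na + nd / 2, dp),
    Gle = sdiv(2 * na, 2 * da + dbc),
    Ja  = sdiv(3 * na, 3 * da + dbc),
    Ja0 = sdiv(3 * (na + nd), 3 * (da + dd) + dbc),
    AC  = (2 / pi) * asin(sqrt(pmin(sdiv(na + nd, dp), 1))),
    BUB = sdiv(sqrt(na * nd) + na, sqrt(da * dd) + da + dbc),
    SS1 = sdiv(na, da + 2 * dbc),
    SS2 = sdiv(2 * (na + nd), dp + da + dd),
    abort(sprintf("unknown index: %s", index))
  )
  if (warn_zero && zero_div) {
    warn(sprintf("index %s: 0/0 form encountered; defined as 0.", index))
  }
  val
}

# Index values for many column-sum vectors (rows of `sums`) sharing one
# object count.  Processed in row blocks so the classification temporaries
# stay cache-resident even for very large candidate pools; the block size
# only affects speed, never the values.
index_over_sums <- function(sums, n, index, gamma = 0, weighted = FALSE,
                            chunk = 1024L) {
  nr <- nrow(sums)
  out <- numeric(nr)
  start <- 1L
  while (start <= nr) {
    end <- min(start + chunk - 1L, nr)
    k <- counters_kernel(sums[start:end, , drop = FALSE], n, gamma)
    out[start:end] <- index_kernel(k, index, weighted = weighted)
    start <- end + 1L
  }
  out
}

#' Evaluate an extended similarity index from counters
#'
#' Applies one of the sixteen index formulas to a counter set.  The weighted
#' counters enter the numerators; the denominators use the raw column counts
#' (default, "nonweighted" family) or the weighted counters (when the
#' counter set was built with `weighted = TRUE`).  All indices map to
#' \eqn{[0,1]}; an undefined 0/0 form (e.g. Jaccard-Tanimoto with
#' `a = bc = 0`) is defined as 0 with a warning.
#'
#' @param counters An `ecs_counters` object from [classify_counters()].
#' @param index Index name (see [ecs_indices()]); case-insensitive.
#' @return The index value, a number in \eqn{[0,1]}.
#' @examples
#' cs <- structure(list(sums = c(2, 2, 0, 1), n_objects = 2L),
#'                 class = "ecs_colsums")
#' extended_similarity(classify_counters(cs), "JT")  # 2/3
#' @export
extended_similarity <- function(counters, index) {
  stopifnot(inherits(counters, "ecs_counters"))
  index <- match_index(index)
  if (counters$p <= 0) abort("counter total p must be positive.")
  index_kernel(counters, index, weighted = counters$weighted,
               warn_zero = TRUE)
}

#' Extended similarity of a whole set of frames
#'
#' Composition of the full pipeline: global min-max normalization, column
#' sums, counter classification and index evaluation, yielding one number in
#' \eqn{[0,1]} that measures how alike *all* \eqn{N} frames are
#' simultaneously — no pairwise comparisons involved, total cost
#' \eqn{O(Nm)}.  When `x` is already an `ecs_norm` (e.g. a subset of a
#' globally normalized trajectory) the normalization step is skipped so that
#' subset values remain comparable across steps.
#'
#' @param x Frames (`ecs_frames`, matrix, data frame) or an `ecs_norm`.
#' @param index Index name; case-insensitive.
#' @param gamma Coincidence threshold, default 0.
#' @param weighted Weighted counters, default `FALSE`.
#' @return The extended similarity, a number in \eqn{[0,1]}.
#' @examples
#' similarity_of_set(rbind(c(1, 1, 0, 1), c(1, 0, 0, 1)), index = "JT")
#' @export
similarity_of_set <- function(x, index = "RT", gamma = 0, weighted = FALSE) {
  norm <- as_norm(x)
  if (nrow(norm$values) < 2L) abort("similarity undefined for fewer than two objects")
  extended_similarity(classify_counters(column_sums(norm), gamma, weighted),
                      index)
}

#' Extended similarity for every index at once
#'
#' @inheritParams similarity_of_set
#' @param indices Character vector of index names or `"all"` (default).
#' @return A tibble with columns `index` and `similarity`.
#' @export
similarity_profile <- function(x, indices = "all", gamma = 0, weighted = FALSE) {
  indices <- match_index(indices, several.ok = TRUE)
  norm <- as_norm(x)
  if (nrow(norm$values) < 2L) abort("similarity undefined for fewer than two objects")
  counters <- classify_counters(column_sums(norm), gamma, weighted)
  vals <- vapply(indices, function(ix) {
    suppressWarnings(extended_similarity(counters, ix))
  }, numeric(1L))
  tibble::tibble(index = indices, similarity = unname(vals))
}

#' Pairwise similarity of two frames under a shared global scaling
#'
#' The two-object special case of the extended similarity, evaluated on two
#' rows of an already-normalized matrix.  The rows are *not* renormalized:
#' reusing the full-set global min/max is what keeps pair values comparable
#' with the growing-set values during selection.
#'
#' @param norm An `ecs_norm` object for the full trajectory.
#' @param i,j Frame row indices (1-based).
#' @inheritParams similarity_of_set
#' @return The pairwise similarity, a number in \eqn{[0,1]}.
#' @export
pairwise_similarity <- function(norm, i, j, index = "RT", gamma = 0,
                                weighted = FALSE) {
  stopifnot(inherits(norm, "ecs_norm"))
  index <- match_index(index)
  ra <- norm$values[i, ]
  rb <- norm$values[j, ]
  if (length(ra) != length(rb)) abort("mismatched row lengths.")
  k <- counters_kernel(ra + rb, 2L, gamma)
  index_kernel(k, index, weighted = weighted)
}
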