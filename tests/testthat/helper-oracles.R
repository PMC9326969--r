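# Independent oracles and tiny fixture builders shared across the suite.

# Classical binary association coefficients, computed directly from the
# 2x2 contingency counts of a pair of {0,1}-vectors.  This is the
# independent reference the extended machinery must reduce to for N = 2.
binary_pair_coefficient <- function(x, y, index) {
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  p <- a + b + c + d
  bc <- b + c
  div0 <- function(num, den) if (den == 0) 0 else num / den
  switch(index,
    RR  = a / p,
    SM  = (a + d) / p,
    JT  = div0(a, a + bc),
    RT  = (a + d) / (p + bc),
    CT1 = log(1 + a + d) / log(1 + p),
    CT2 = (log(1 + p) - log(1 + bc)) / log(1 + p),
    CT3 = log(1 + a) / log(1 + p),
    CT4 = div0(log(1 + a), log(1 + a + bc)),
    Fai = (a + d / 2) / p,
    Gle = div0(2 * a, 2 * a + bc),
    Ja  = div0(3 * a, 3 * a + bc),
    Ja0 = div0(3 * (a + d), 3 * (a + d) + bc),
    AC  = (2 / pi) * asin(sqrt((a + d) / p)),
    BUB = div0(sqrt(a * d) + a, sqrt(a * d) + a + bc),
    SS1 = div0(a, a + 2 * bc),
    SS2 = 2 * (a + d) / (p + a + d),
    stop("unknown index in oracle: ", index)
  )
}

# A subset view of a normalized matrix that keeps the global scaling
# (no renormalization), as required for leave-one-out / growing-set values.
sub_norm <- function(norm, rows) {
  norm$values <- norm$values[rows, , drop = FALSE]
  norm$n_frames <- length(rows)
  norm
}

# Brute-force leave-one-out: recompute the extended similarity of every
# N-1 subset from scratch.
naive_complementary <- function(norm, index, gamma = 0, weighted = FALSE) {
  n <- nrow(norm$values)
  vapply(seq_len(n), function(i) {
    suppressWarnings(
      similarity_of_set(sub_norm(norm, setdiff(seq_len(n), i)),
                        index = index, gamma = gamma, weighted = weighted))
  }, numeric(1L))
}

# From-scratch ECS-MeDiv: at every step the extended similarity of
# (selected + candidate) is recomputed with similarity_of_set on the
# explicit submatrix, and the pairwise tiebreak likewise.  No incremental
# column-sum bookkeeping anywhere.
naive_mediv <- function(norm, n_select, index, gamma = 0, weighted = FALSE,
                        tie_tol = 1e-12) {
  n <- nrow(norm$values)
  comp <- naive_complementary(norm, index, gamma, weighted)
  order <- which.min(comp)
  sims <- NA_real_
  while (length(order) < n_select) {
    cand <- setdiff(seq_len(n), order)
    vals <- vapply(cand, function(cc) {
      suppressWarnings(similarity_of_set(sub_norm(norm, c(order, cc)),
                                         index = index, gamma = gamma,
                                         weighted = weighted))
    }, numeric(1L))
    mn <- min(vals)
    tied <- cand[vals <= mn + tie_tol]
    if (length(tied) > 1L) {
      mp <- vapply(tied, function(t) {
        mean(vapply(order, function(s) {
          suppressWarnings(similarity_of_set(sub_norm(norm, c(s, t)),
                                             index = index, gamma = gamma,
                                             weighted = weighted))
        }, numeric(1L)))
      }, numeric(1L))
      pick <- tied[which.min(mp)]
    } else {
      pick <- tied[[1L]]
    }
    sims <- c(sims, vals[match(pick, cand)])
    order <- c(order, pick)
  }
  list(order = as.integer(order), step_similarity = sims)
}

# Counter sets with prescribed raw counts whose weights are exactly 1
# (binary-style column sums for an even object count), so raw and weighted
# counters coincide: a columns sum to n, d columns to 0, bc columns to n/2.
counters_from_counts <- function(a, d, bc, n = 2L) {
  sums <- c(rep(n, a), rep(0, d), rep(n / 2, bc))
  cs <- structure(list(sums = sums, n_objects = as.integer(n)),
                  class = "ecs_colsums")
  classify_counters(cs)
}

# Multi-model PDB text with one GLY residue per atom triple.  `models` is a
# list of data frames with columns name, resno, x, y, z and optional alt.
make_pdb_lines <- function(models) {
  lines <- character(0)
  for (i in seq_along(models)) {
    mdl <- models[[i]]
    if (is.null(mdl$alt)) mdl$alt <- " "
    lines <- c(lines, sprintf("MODEL     %4d", i))
    for (j in seq_len(nrow(mdl))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        j, mdl$name[[j]], mdl$alt[[j]], "GLY", "A", mdl$resno[[j]],
        mdl$x[[j]], mdl$y[[j]], mdl$z[[j]], 1, 0,
        substr(trimws(mdl$name[[j]]), 1L, 1L)))
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

gly_model <- function(z = 0, names = c("N", "CA", "C")) {
  data.frame(name = names, resno = 1L,
             x = seq_along(names), y = 0, z = z)
}
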