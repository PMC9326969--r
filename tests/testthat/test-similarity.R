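test_that("min-max normalization uses one global extrema pair", {
  nrm <- normalize_frames(rbind(c(0, 2, 0), c(4, 2, 0)))
  expect_equal(nrm$global_min, 0)
  expect_equal(nrm$global_max, 4)
  expect_equal(nrm$values, rbind(c(0, 0.5, 0), c(1, 0.5, 0)))

  # a {0,1} matrix containing both extremes is a fixed point
  b <- rbind(c(0, 1, 1), c(1, 0, 0))
  expect_equal(normalize_frames(b)$values, b)

  # constant matrix: documented degenerate rule, all zeros
  k <- normalize_frames(rbind(c(3, 3, 3), c(3, 3, 3)))
  expect_equal(k$values, matrix(0, 2, 3))

  expect_error(normalize_frames(rbind(c(1, NA, 0))), "finite")
})

test_that("normalization round-trips to the original coordinates", {
  set.seed(11)
  v <- matrix(rnorm(60, sd = 8), nrow = 5)
  nrm <- normalize_frames(v)
  expect_true(all(nrm$values >= 0 & nrm$values <= 1))
  expect_equal(nrm$values * (nrm$global_max - nrm$global_min) + nrm$global_min,
               v, tolerance = 1e-12)
})

test_that("column sums condense the set and respect linearity", {
  cs <- column_sums(normalize_frames(rbind(c(0, 2, 0), c(4, 2, 0))))
  expect_equal(cs$sums, c(1, 1, 0))
  expect_equal(cs$n_objects, 2L)

  r <- c(0.2, 0.8, 0.5)
  rep5 <- normalize_frames(rbind(r, r, r, r, r))
  # identical rows: sums are N times the (normalized) row
  expect_equal(column_sums(rep5)$sums, 5 * rep5$values[1, ])
})

test_that("counter classification partitions columns and weights them", {
  cs <- structure(list(sums = c(2, 0, 1, 1.6), n_objects = 2L),
                  class = "ecs_colsums")
  ct <- classify_counters(cs, gamma = 0)
  expect_equal(ct$a, 2)   # sums 2 and 1.6 agree high
  expect_equal(ct$d, 1)   # sum 0 agrees low
  expect_equal(ct$bc, 1)  # sum 1 carries no consensus (delta = 0)
  expect_equal(ct$p, 4)
  # fraction weights: delta/N for similarity columns
  expect_equal(ct$w_a, 1 + 0.6)
  expect_equal(ct$w_d, 1)
  expect_equal(ct$w_bc, 1)

  # delta = 0 is never > gamma = 0
  ct2 <- classify_counters(structure(list(sums = c(1, 1), n_objects = 2L),
                                     class = "ecs_colsums"))
  expect_equal(c(ct2$a, ct2$d, ct2$bc), c(0, 0, 2))

  expect_error(classify_counters(structure(list(sums = 1, n_objects = 1L),
                                           class = "ecs_colsums")),
               "fewer than two")
  expect_error(classify_counters(cs, gamma = -1), "gamma")
})

test_that("raw counters always partition the columns", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    m <- sample(5:40, 1)
    sums <- runif(m, 0, n)
    cs <- structure(list(sums = sums, n_objects = n), class = "ecs_colsums")
    for (g in c(0, 0.5)) {
      ct <- classify_counters(cs, gamma = g)
      expect_equal(ct$a + ct$d + ct$bc, m)
      expect_equal(ct$p, m)
      expect_equal(ct$w_a + ct$w_d + ct$w_bc, ct$w_p)
      expect_true(all(c(ct$a, ct$d, ct$bc, ct$w_a, ct$w_d, ct$w_bc) >= 0))
    }
  }
})

test_that("index formulas reproduce hand-computed counter arithmetic", {
  ct <- counters_from_counts(a = 2, d = 1, bc = 1)
  expect_equal(extended_similarity(ct, "JT"), 2 / 3)
  expect_equal(extended_similarity(ct, "RT"), 0.6)
  expect_equal(extended_similarity(ct, "SM"), 0.75)
  expect_equal(extended_similarity(ct, "CT2"), (log(5) - log(2)) / log(5))
  expect_equal(extended_similarity(ct, "Fai"), 2.5 / 4)
  expect_equal(extended_similarity(ct, "SS1"), 2 / 4)
  expect_equal(extended_similarity(ct, "BUB"),
               (sqrt(2) + 2) / (sqrt(2) + 3))

  # perfect similarity: every column a 1-similarity column
  perf <- counters_from_counts(a = 10, d = 0, bc = 0)
  for (ix in c("JT", "RT", "SM", "RR", "CT2")) {
    expect_equal(extended_similarity(perf, ix), 1)
  }

  # total dissimilarity
  none <- counters_from_counts(a = 0, d = 0, bc = 10)
  for (ix in c("JT", "CT2", "SM")) {
    expect_equal(suppressWarnings(extended_similarity(none, ix)), 0)
  }
})

test_that("0/0 index forms are defined as 0 with a warning", {
  none <- counters_from_counts(a = 0, d = 5, bc = 0)
  expect_warning(val <- extended_similarity(none, "JT"), "0/0")
  expect_equal(val, 0)
  expect_warning(extended_similarity(counters_from_counts(0, 8, 0), "BUB"))
})

test_that("index names are matched case-insensitively and 'all' expands", {
  expect_equal(similarity_profile(rbind(c(1, 1, 0), c(1, 0, 0)))$index,
               ecs_indices())
  v <- rbind(c(1, 1, 0, 1), c(1, 0, 0, 1))
  expect_equal(similarity_of_set(v, index = "jt"),
               similarity_of_set(v, index = "JT"))
  expect_error(similarity_of_set(v, index = "nope"), "unknown similarity index")
  expect_error(similarity_of_set(v, index = "all"), "single index")
})

test_that("binary two-object limit reproduces the classical coefficients", {
  set.seed(7)
  for (rep in 1:60) {
    m <- 50L
    x <- rbinom(m, 1, runif(1, 0.2, 0.8))
    y <- rbinom(m, 1, runif(1, 0.2, 0.8))
    if (max(x, y) == 0 || min(x, y) == 1) next  # needs both extremes present
    for (ix in ecs_indices()) {
      got <- suppressWarnings(similarity_of_set(rbind(x, y), index = ix))
      expect_equal(got, binary_pair_coefficient(x, y, ix), tolerance = 1e-12,
                   label = sprintf("index %s", ix))
    }
  }
})

test_that("whole-set similarity is invariant to row and column permutation", {
  set.seed(21)
  v <- matrix(runif(10 * 12), nrow = 10)
  base <- sapply(ecs_indices(), function(ix) similarity_of_set(v, index = ix))
  for (rep in 1:5) {
    vr <- v[sample(nrow(v)), sample(ncol(v))]
    got <- sapply(ecs_indices(), function(ix) similarity_of_set(vr, index = ix))
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("all indices stay within [0, 1] on random counter sets", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    sums <- runif(25, 0, n)
    cs <- structure(list(sums = sums, n_objects = n), class = "ecs_colsums")
    for (w in c(FALSE, TRUE)) {
      ct <- classify_counters(cs, weighted = w)
      vals <- sapply(ecs_indices(), function(ix) {
        suppressWarnings(extended_similarity(ct, ix))
      })
      expect_true(all(vals >= 0 & vals <= 1),
                  info = sprintf("n=%d weighted=%s min=%g max=%g",
                                 n, w, min(vals), max(vals)))
    }
  }
})

test_that("min-max scaling preserves every L1 distance ordering exactly", {
  # the normalization is one affine map, so all L1 distances are scaled by
  # the same positive constant and comparisons between frame pairs are
  # preserved exactly, not just approximately
  set.seed(5)
  v <- matrix(rnorm(8 * 15, sd = 6), nrow = 8)
  nrm <- normalize_frames(v)
  l1 <- function(mat, i, j) sum(abs(mat[i, ] - mat[j, ]))
  for (rep in 1:200) {
    q <- sample(8, 4)
    before <- l1(v, q[1], q[2]) - l1(v, q[3], q[4])
    after <- l1(nrm$values, q[1], q[2]) - l1(nrm$values, q[3], q[4])
    expect_equal(sign(before), sign(after))
  }
})

test_that("growing a at fixed d and bc strictly increases a-driven indices", {
  for (d in c(0, 3)) {
    for (bc in c(1, 4)) {
      for (ix in c("JT", "RR", "CT3", "CT4")) {
        vals <- sapply(1:6, function(a) {
          suppressWarnings(extended_similarity(
            counters_from_counts(a, d, bc, n = 2L), ix))
        })
        expect_true(all(diff(vals) > 0),
                    info = sprintf("%s d=%d bc=%d", ix, d, bc))
      }
    }
  }
})

test_that("pairwise similarity reuses the global scaling", {
  nrm <- normalize_frames(rbind(c(1, 1, 0, 1), c(1, 0, 0, 1), c(0, 0, 0, 0)))
  expect_equal(pairwise_similarity(nrm, 1, 2, index = "JT"), 2 / 3)
  # identical extreme rows are perfectly similar
  nrm2 <- normalize_frames(rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(pairwise_similarity(nrm2, 1, 2, index = "SM"), 1)
  expect_equal(pairwise_similarity(nrm2, 1, 2, index = "RT"), 1)
  # complementary binary rows share nothing
  nrm3 <- normalize_frames(rbind(c(1, 0), c(0, 1)))
  expect_equal(suppressWarnings(pairwise_similarity(nrm3, 1, 2, index = "JT")), 0)
})

test_that("similarity requires at least two frames", {
  expect_error(similarity_of_set(matrix(runif(5), nrow = 1)), "fewer than two")
  expect_error(similarity_profile(matrix(runif(5), nrow = 1)), "fewer than two")
})
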