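test_that("sample distances match the closed form and a brute-force oracle", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  colnames(m) <- c("f1", "f2")
  D <- sample_distance_matrix(m)
  expect_equal(D["a", "b"], sqrt(2))
  expect_equal(D["a", "c"], 0)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))

  set.seed(11)
  X <- matrix(runif(15), 5, 3,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:3)))
  D <- sample_distance_matrix(X)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D[i, j], sqrt(sum((X[i, ] - X[j, ])^2)))
  }
  bad <- X; bad[2, 2] <- NaN
  expect_error(sample_distance_matrix(bad), "non-finite")
})

test_that("kNN sets include self, break ties by index, and respect k bounds", {
  # three equidistant items
  D <- matrix(1, 3, 3); diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  ns <- knn_neighbor_sets(D, 1L)
  expect_equal(ns$sets, list(c(1L, 2L), c(1L, 2L), c(1L, 3L)))

  # 1-D chain at 0, 1, 10
  D <- as.matrix(dist(c(0, 1, 10)))
  ns <- knn_neighbor_sets(D, 1L)
  expect_equal(ns$sets, list(c(1L, 2L), c(1L, 2L), c(2L, 3L)))

  # k = N - 1 gives the full item set everywhere
  ns <- knn_neighbor_sets(D, 2L)
  expect_true(all(vapply(ns$sets, identical, logical(1), 1:3)))
  expect_error(knn_neighbor_sets(D, 0L), "k must be")
  expect_error(knn_neighbor_sets(D, 3L), "k must be")
})

test_that("Jaccard similarity of neighbor sets follows |intersection|/|union|", {
  ns <- structure(list(sets = list(c(1L, 2L, 3L), c(2L, 3L, 4L),
                                   c(5L, 6L, 7L), c(1L, 2L, 3L)),
                       k = 2L, ids = paste0("s", 1:4)),
                  class = "neighbor_sets")
  J <- jaccard_from_neighbors(ns)
  expect_equal(J[1, 2], 0.5)        # {1,2,3} vs {2,3,4}: 2/4
  expect_equal(J[1, 3], 0)          # disjoint
  expect_equal(J[1, 4], 1)          # identical sets
  expect_equal(diag(J), setNames(rep(1, 4), paste0("s", 1:4)))
  expect_true(all(J >= 0 & J <= 1))
  expect_equal(J, t(J))
})

test_that("SNN similarity is invariant to item reordering up to permutation", {
  set.seed(21)
  X <- matrix(runif(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  J1 <- snn_similarity(sample_distance_matrix(X), k = 3L)
  perm <- sample(10)
  J2 <- snn_similarity(sample_distance_matrix(X[perm, ]), k = 3L)
  expect_equal(J2[rownames(J1), colnames(J1)], J1)
})

test_that("DTW reproduces its closed-form examples", {
  expect_equal(dtw_distance(matrix(1:3), matrix(1:3)), 0)
  # repetition absorbs the duplicated element
  expect_equal(dtw_distance(matrix(c(1, 2, 3)), matrix(c(1, 2, 2, 3))), 0)
  # hand-checked DP table (1,2; 3,3)
  expect_equal(dtw_distance(matrix(c(0, 3)), matrix(c(1, 1))), 3)
  expect_error(
    dtw_distance(matrix(1:2, ncol = 1, dimnames = list(NULL, "f1")),
                 matrix(1:4, ncol = 2,
                        dimnames = list(NULL, c("f1", "f2")))),
    "mismatched family")
})

test_that("DTW is symmetric, nonnegative, zero on identity, diagonal-bounded", {
  set.seed(31)
  for (r in 1:25) {
    p <- random_series_pair(max_len = 5L, max_fam = 3L)
    d_ab <- dtw_distance(p$a, p$b)
    expect_gte(d_ab, 0)
    expect_equal(d_ab, dtw_distance(p$b, p$a))
    expect_equal(dtw_distance(p$a, p$a), 0)
  }
  # equal-length series: DTW never exceeds the diagonal alignment cost
  for (r in 1:10) {
    nf <- 3L
    a <- matrix(runif(4 * nf), 4, nf); a <- a / rowSums(a)
    b <- matrix(runif(4 * nf), 4, nf); b <- b / rowSums(b)
    diag_cost <- sum(sqrt(rowSums((a - b)^2)))
    expect_lte(dtw_distance(a, b), diag_cost + 1e-12)
  }
})

test_that("DTW equals the exhaustive warping-path minimum on random pairs", {
  set.seed(41)
  for (r in 1:30) {
    p <- random_series_pair()
    expect_equal(dtw_distance(p$a, p$b), dtw_enum_oracle(p$a, p$b),
                 tolerance = 1e-12)
  }
})

test_that("path-length normalization and band options behave sanely", {
  set.seed(51)
  p <- random_series_pair(max_len = 5L, max_fam = 3L)
  raw <- dtw_distance(p$a, p$b)
  norm <- dtw_distance(p$a, p$b, normalize = TRUE)
  expect_lte(norm, raw + 1e-12)
  wide <- dtw_distance(p$a, p$b, band = max(nrow(p$a), nrow(p$b)))
  expect_equal(wide, raw)
})

test_that("series distance matrix composes DTW pairwise", {
  mk <- function(id, mat) {
    microbiota_series(id, "i", "sp", "z", seq_len(nrow(mat)),
                      mat / rowSums(mat))
  }
  set.seed(61)
  base <- matrix(runif(12), 4, 3,
                 dimnames = list(NULL, paste0("f", 1:3)))
  s1 <- mk("a", base); s2 <- mk("b", base)
  m3 <- matrix(runif(9), 3, 3, dimnames = list(NULL, paste0("f", 1:3)))
  s3 <- mk("c", m3)
  D <- series_distance_matrix(list(s1, s2, s3))
  expect_equal(D["a", "b"], 0)   # duplicated series
  expect_equal(D["a", "c"], dtw_distance(s1, s3))
  expect_equal(D, t(D))
  expect_error(series_distance_matrix(list(s1)), "at least 2")

  # constant orthogonal profiles: diagonal path is optimal, distance is the
  # per-day Euclidean cost summed over the (equal) series length
  e1 <- matrix(rep(c(1, 0, 0), each = 3), 3, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  e2 <- matrix(rep(c(0, 1, 0), each = 3), 3, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  o1 <- mk("o1", e1); o2 <- mk("o2", e2)
  D2 <- series_distance_matrix(list(o1, o2))
  expect_equal(D2["o1", "o2"], 3 * sqrt(2))
})
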