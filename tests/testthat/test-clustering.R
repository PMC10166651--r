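test_that("similarity to dissimilarity is the elementwise complement", {
  J <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  D <- similarity_to_dissimilarity(J)
  expect_equal(D["a", "b"], 0.6)
  expect_equal(diag(D), c(a = 0, b = 0))
  expect_equal(D, t(D))
  expect_equal(similarity_to_dissimilarity(diag(2))[1, 2], 1)
})

test_that("Ward merges nearby 1-D pairs first and handles identical items", {
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  dimnames(D) <- list(paste0("x", 1:4), paste0("x", 1:4))
  w <- ward_linkage(D)
  steps <- ward_steps(w)
  expect_equal(steps[[1]]$a, 1L)
  expect_equal(steps[[1]]$b, 2L)
  expect_equal(steps[[2]]$a, 3L)
  expect_equal(steps[[2]]$b, 4L)

  same <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w0 <- ward_linkage(same)
  expect_equal(w0$height, c(0, 0))

  bad <- D; bad[1, 2] <- NA
  expect_error(ward_linkage(bad), "non-finite")
})

test_that("Ward merge sequences and heights match the from-scratch ESS oracle", {
  set.seed(71)
  for (r in 1:10) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    rownames(X) <- paste0("s", seq_len(n))
    w <- ward_linkage(as.matrix(dist(X)))
    oracle <- ward_ess_oracle(X)
    expect_equal(ward_steps(w), oracle$steps)
    expect_equal(w$height, oracle$heights, tolerance = 1e-8)
    expect_true(all(diff(w$height) >= -1e-12))   # Ward monotonicity
  }
})

test_that("height-gap cut finds planted cluster counts and honors min_clusters", {
  # dominant 2-cluster gap
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  dimnames(D) <- list(paste0("x", 1:4), paste0("x", 1:4))
  lab <- cut_by_height_gap(ward_linkage(D), 2L)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(lab[["x1"]], lab[["x2"]])
  expect_equal(lab[["x3"]], lab[["x4"]])
  expect_false(lab[["x1"]] == lab[["x3"]])

  # three well-separated triplets with min_clusters 3
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2, 20, 20.1, 20.2)
  D3 <- as.matrix(dist(pts))
  dimnames(D3) <- list(paste0("p", 1:9), paste0("p", 1:9))
  lab3 <- cut_by_height_gap(ward_linkage(D3), 3L)
  expect_equal(length(unique(lab3)), 3L)
  expect_equal(unname(lab3), rep(1:3, each = 3))

  # N == min_clusters: only the all-singleton solution is admissible
  Ds <- as.matrix(dist(c(0, 5, 9)))
  dimnames(Ds) <- list(letters[1:3], letters[1:3])
  labs <- cut_by_height_gap(ward_linkage(Ds), 3L)
  expect_equal(unname(labs), 1:3)

  expect_error(cut_by_height_gap(ward_linkage(Ds), 2L) -> l2, NA)
  expect_gte(length(unique(l2)), 2L)
  D2 <- as.matrix(dist(c(0, 1)))
  dimnames(D2) <- list(c("a", "b"), c("a", "b"))
  expect_error(cut_by_height_gap(ward_linkage(D2), 3L), "no admissible cut")
})

test_that("community detection solves the canonical fixtures exactly", {
  edges <- function(n, pairs) {
    W <- matrix(0, n, n)
    for (p in pairs) W[p[1], p[2]] <- W[p[2], p[1]] <- 1
    dimnames(W) <- list(paste0("v", 1:n), paste0("v", 1:n))
    W
  }
  # two disconnected unit triangles: Q = 0.5
  tri2 <- edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
  lab <- community_detection(tri2)
  expect_equal(attr(lab, "modularity"), 0.5)
  expect_equal(as.integer(lab), rep(1:2, each = 3))

  # complete graph on 4 nodes: single community, Q = 0
  K4 <- edges(4, combn(4, 2, simplify = FALSE))
  lab4 <- community_detection(K4)
  expect_equal(attr(lab4, "modularity"), 0, tolerance = 1e-12)
  expect_equal(length(unique(lab4)), 1L)

  # disconnected cliques of size 3 and 4
  cl <- edges(7, c(combn(3, 2, simplify = FALSE),
                   lapply(combn(4:7, 2, simplify = FALSE), identity)))
  lab7 <- community_detection(cl)
  expect_equal(length(unique(lab7)), 2L)
  expect_equal(as.integer(lab7), c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  expect_equal(attr(lab7, "modularity"), modularity_max_oracle(cl))

  # empty graph: all singletons with a warning
  expect_warning(lab0 <- community_detection(diag(5)), "no edges")
  expect_equal(length(unique(lab0)), 5L)
})

test_that("achieved modularity agrees with igraph on the pipeline's graphs", {
  set.seed(81)
  A <- matrix(runif(48), 12, 4,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:4)))
  A <- A / rowSums(A)
  J <- snn_similarity(sample_distance_matrix(A))
  lab <- community_detection(J)
  W <- J; diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(attr(lab, "modularity"),
               igraph::modularity(g, unname(lab),
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("greedy modularity beats the trivial partitions on random graphs", {
  set.seed(91)
  for (r in 1:15) {
    n <- sample(5:8, 1)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- runif(1)
    }
    if (sum(W) == 0) next
    dimnames(W) <- list(paste0("v", 1:n), paste0("v", 1:n))
    lab <- suppressWarnings(community_detection(W))
    q <- attr(lab, "modularity")
    q_single <- modularity_direct(W, seq_len(n))
    q_one <- modularity_direct(W, rep(1L, n))
    expect_gte(q, max(q_single, q_one) - 1e-12)
    # the reported Q matches the independent double-sum formula
    expect_equal(q, modularity_direct(W, unname(lab)), tolerance = 1e-12)
  }
})

test_that("both clusterers are deterministic on identical input", {
  set.seed(101)
  A <- matrix(runif(60), 15, 4,
              dimnames = list(paste0("s", 1:15), paste0("f", 1:4)))
  A <- A / rowSums(A)
  J <- snn_similarity(sample_distance_matrix(A))
  w1 <- cut_by_height_gap(ward_linkage(similarity_to_dissimilarity(J)), 2L)
  w2 <- cut_by_height_gap(ward_linkage(similarity_to_dissimilarity(J)), 2L)
  expect_identical(w1, w2)
  c1 <- community_detection(J)
  c2 <- community_detection(J)
  expect_identical(c1, c2)
})
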