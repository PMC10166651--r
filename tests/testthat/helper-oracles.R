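# Independent oracles used by the property and acceptance tests. All are
# deliberately naive (enumeration / from-scratch recomputation) and share no
# code with the package internals.

# DTW: minimum cumulative Euclidean cost over all monotone warping paths,
# by exhaustive recursion (no DP table). Feasible for lengths <= ~6.
dtw_enum_oracle <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  cost <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1L && j == 1L) return(c0)
    best <- Inf
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    c0 + best
  }
  rec(nrow(A), nrow(B))
}

# Ward: greedy merging recomputing the ESS increase from scratch (from the
# point coordinates) for every candidate pair at every step. Ties broken by
# the smallest (min-member-a, min-member-b) pair, as declared by the package.
ward_ess_oracle <- function(X) {
  n <- nrow(X)
  ess <- function(idx) {
    if (length(idx) < 2L) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2L, ctr)^2)
  }
  clusters <- as.list(seq_len(n))
  steps <- vector("list", n - 1L)
  heights <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        better <- d < best - 1e-12
        tie <- abs(d - best) <= 1e-12
        if (tie) {
          cur <- sort(c(min(clusters[[bi]]), min(clusters[[bj]])))
          new <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          better <- new[1L] < cur[1L] ||
            (new[1L] == cur[1L] && new[2L] < cur[2L])
        }
        if (better) { best <- d; bi <- i; bj <- j }
      }
    }
    a <- sort(clusters[[bi]]); b <- sort(clusters[[bj]])
    if (min(b) < min(a)) { tmp <- a; a <- b; b <- tmp }
    steps[[s]] <- list(a = a, b = b)
    heights[s] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(steps = steps, heights = heights)
}

# Reconstruct per-step member sets from an hclust-style merge matrix.
ward_steps <- function(tree) {
  merge <- tree$merge
  members <- vector("list", nrow(merge))
  steps <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    grab <- function(code) if (code < 0L) -code else members[[code]]
    a <- sort(grab(merge[s, 1L])); b <- sort(grab(merge[s, 2L]))
    if (min(b) < min(a)) { tmp <- a; a <- b; b <- tmp }
    steps[[s]] <- list(a = a, b = b)
    members[[s]] <- c(a, b)
  }
  steps
}

# All set partitions of 1..n as restricted-growth membership vectors.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxb) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return()
    }
    for (b in seq_len(maxb + 1L)) rec(c(assign, b), max(maxb, b))
  }
  rec(1L, 1L)
  out
}

# Weighted modularity by the direct double sum (independent of the package's
# community bookkeeping).
modularity_direct <- function(W, memb) {
  diag(W) <- 0
  m2 <- sum(W)
  k <- rowSums(W)
  n <- nrow(W)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) s <- s + W[i, j] - k[i] * k[j] / m2
    }
  }
  as.numeric(s / m2)
}

# Exhaustive-partition modularity maximum.
modularity_max_oracle <- function(W) {
  parts <- all_partitions(nrow(W))
  max(vapply(parts, function(p) modularity_direct(W, p), numeric(1)))
}

# Mean silhouette width over Euclidean distances.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small random series pair with a shared family universe, rows summing to 1.
random_series_pair <- function(max_len = 5L, max_fam = 3L) {
  nf <- sample.int(max_fam, 1L)
  make <- function() {
    nd <- sample.int(max_len, 1L)
    m <- matrix(stats::runif(nd * nf), nd, nf)
    m / rowSums(m)
  }
  list(a = make(), b = make())
}
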