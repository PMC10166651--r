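#' Convert a Jaccard similarity matrix to a dissimilarity matrix
#'
#' Elementwise `d = 1 - J`; bridges the similarity-graph representation and
#' Ward's distance-based merge criterion.
#'
#' @param S Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @return Dissimilarity matrix with zero diagonal.
#' @export
similarity_to_dissimilarity <- function(S) {
  D <- 1 - S
  diag(D) <- 0
  D
}

#' Ward's agglomerative linkage on a precomputed dissimilarity
#'
#' Agglomerative clustering under Ward's criterion: at every step the pair of
#' clusters whose merge gives the minimal increase in error sum of squares
#' (ESS) is joined. The ESS increase is propagated with the Lance-Williams
#' recurrence
#' \deqn{\Delta(A \cup B, C) = \frac{(n_A + n_C)\Delta(A,C) +
#'   (n_B + n_C)\Delta(B,C) - n_C \Delta(A,B)}{n_A + n_B + n_C}}
#' initialized from singleton pairs as \eqn{\Delta(\{i\},\{j\}) = d_{ij}^2/2},
#' the "Ward on precomputed dissimilarity" convention. Merge ties are broken
#' by the lexicographically smallest pair of cluster representatives (each
#' cluster represented by its smallest original item index).
#'
#' @param D Symmetric dissimilarity matrix, zero diagonal, no missing values.
#' @return An object of classes `ward_dendrogram` and `hclust` (so
#'   `stats::cutree()` and `plot()` work): `merge`, `height` (the ESS
#'   increase of each merge, non-decreasing), `order`, `labels`.
#' @export
ward_linkage <- function(D) {
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items")
  if (any(!is.finite(D))) stop("non-finite value in dissimilarity matrix")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cost <- D^2 / 2
  diag(cost) <- Inf
  active <- seq_len(n)
  size <- rep(1L, n)
  rep_id <- seq_len(n)        # smallest original member, for tie-breaking
  code <- -seq_len(n)         # hclust coding: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- cost[active, active, drop = FALSE]
    best <- min(sub)
    idx <- which(sub == best, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    # tie-break: smallest (rep_a, rep_b) with rep_a < rep_b
    ra <- pmin(rep_id[active[idx[, 1L]]], rep_id[active[idx[, 2L]]])
    rb <- pmax(rep_id[active[idx[, 1L]]], rep_id[active[idx[, 2L]]])
    pick <- order(ra, rb)[1L]
    i <- active[idx[pick, 1L]]
    j <- active[idx[pick, 2L]]
    if (rep_id[j] < rep_id[i]) { tmp <- i; i <- j; j <- tmp }
    height[step] <- best
    merge[step, ] <- c(code[i], code[j])
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      cost[i, others] <- cost[others, i] <-
        ((ni + nk) * cost[i, others] + (nj + nk) * cost[j, others] -
           nk * best) / (ni + nj + nk)
    }
    size[i] <- size[i] + size[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    code[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge), labels = ids,
                 method = "ward", call = match.call(),
                 dist.method = "precomputed"),
            class = c("ward_dendrogram", "hclust"))
}

dendrogram_order <- function(merge) {
  walk <- function(code) {
    if (code < 0L) return(-code)
    c(walk(merge[code, 1L]), walk(merge[code, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram at the most consistent cluster number
#'
#' Selects the cluster number automatically as the most consistent solution
#' in the dendrogram: for each admissible cut giving `k` clusters
#' (`min_clusters <= k <= N - 1`), the score is the gap between the merge
#' heights just below and just above the cut, and the maximal-gap cut wins
#' (ties toward smaller `k`). Cuts with fewer than `min_clusters` clusters
#' are never returned: species-level runs allow 2 clusters, individual-level
#' runs require at least 3.
#'
#' @param dend A [ward_linkage()] dendrogram.
#' @param min_clusters Minimum admissible cluster count (2 or 3).
#' @return A labeling: named integer vector (cluster ids contiguous from 1,
#'   in order of first appearance).
#' @export
cut_by_height_gap <- function(dend, min_clusters = 2L) {
  n <- length(dend$labels)
  if (!min_clusters %in% c(2L, 3L)) stop("min_clusters must be 2 or 3")
  if (n < min_clusters) {
    stop("no admissible cut: N = ", n, " < min_clusters = ", min_clusters)
  }
  if (n == min_clusters) {
    return(as_labeling(stats::setNames(seq_len(n), dend$labels)))
  }
  h <- dend$height
  ks <- min_clusters:(n - 1L)
  gaps <- h[n - ks + 1L] - h[n - ks]
  k_best <- min(ks[gaps == max(gaps)])
  memb <- stats::cutree(dend, k = k_best)
  as_labeling(memb)
}

# Canonical labeling: cluster ids contiguous from 1 in order of appearance.
as_labeling <- function(x) {
  ids <- names(x)
  out <- match(x, unique(x))
  names(out) <- ids
  out
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c (e_c - a_c^2)` where `e_c` is the fraction of total edge weight
#' inside community `c` and `a_c` the fraction of edge-weight endpoints in
#' `c`.
#'
#' @param W Symmetric nonnegative weight matrix (diagonal ignored).
#' @param membership Integer community id per item.
#' @return Modularity `Q` (NA if the graph has no edges).
#' @export
graph_modularity <- function(W, membership) {
  diag(W) <- 0
  m2 <- sum(W)
  if (m2 == 0) return(NA_real_)
  k <- rowSums(W)
  Q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    Q <- Q + sum(W[in_c, in_c]) / m2 - (sum(k[in_c]) / m2)^2
  }
  Q
}

#' Greedy modularity community detection on a weighted similarity graph
#'
#' Newman-style agglomerative modularity maximization: every item starts as
#' its own community and the merge with the largest modularity gain among
#' connected community pairs is applied repeatedly, generalizing "number of
#' edges" to the Jaccard edge weights the pipeline produces. The partition
#' with maximal modularity along the merge path is returned. Merge ties are
#' broken by the lowest community representatives. Items with no positive
#' similarity to anything stay singletons.
#'
#' @param S Symmetric similarity matrix; off-diagonal entries are edge
#'   weights, zeros mean no edge.
#' @param min_edge_weight Optional sparsification threshold; weights below it
#'   are dropped (default 0 keeps all positive weights).
#' @return A labeling (named integer vector) with attributes `modularity`
#'   (the achieved Q) and `n_communities`.
#' @export
community_detection <- function(S, min_edge_weight = 0) {
  W <- S
  diag(W) <- 0
  W[W < min_edge_weight] <- 0
  n <- nrow(W)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m2 <- sum(W)
  if (m2 == 0) {
    warning("similarity graph has no edges; every item is its own cluster")
    lab <- as_labeling(stats::setNames(seq_len(n), ids))
    attr(lab, "modularity") <- NA_real_
    attr(lab, "n_communities") <- n
    return(lab)
  }
  k <- rowSums(W)
  membership <- seq_len(n)
  active <- seq_len(n)
  B <- W                     # between-community weight
  a <- k / m2
  rep_id <- seq_len(n)
  Q <- -sum(a^2)
  best_Q <- Q
  best_membership <- membership
  repeat {
    if (length(active) < 2L) break
    sub <- B[active, active, drop = FALSE]
    conn <- which(sub > 0, arr.ind = TRUE)
    conn <- conn[conn[, 1L] < conn[, 2L], , drop = FALSE]
    if (nrow(conn) == 0L) break
    ai <- active[conn[, 1L]]
    aj <- active[conn[, 2L]]
    dq <- 2 * (sub[conn] / m2 - a[ai] * a[aj])
    bestdq <- max(dq)
    cand <- which(dq == bestdq)
    ra <- pmin(rep_id[ai[cand]], rep_id[aj[cand]])
    rb <- pmax(rep_id[ai[cand]], rep_id[aj[cand]])
    pick <- cand[order(ra, rb)[1L]]
    i <- ai[pick]; j <- aj[pick]
    if (rep_id[j] < rep_id[i]) { tmp <- i; i <- j; j <- tmp }
    membership[membership == j] <- i
    others <- setdiff(active, c(i, j))
    B[i, others] <- B[others, i] <- B[i, others] + B[j, others]
    a[i] <- a[i] + a[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    active <- setdiff(active, j)
    Q <- Q + bestdq
    if (Q > best_Q + 1e-12) {
      best_Q <- Q
      best_membership <- membership
    }
  }
  lab <- as_labeling(stats::setNames(best_membership, ids))
  attr(lab, "modularity") <- best_Q
  attr(lab, "n_communities") <- length(unique(best_membership))
  lab
}
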