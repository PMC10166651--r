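#' Pairwise Euclidean distances between sample profiles
#'
#' Distance matrix over the rows of an abundance table; the single-clustering
#' branch feeds this into the k-nearest-neighbor / Jaccard construction.
#'
#' @param abundance Samples x families numeric matrix (relative abundances).
#' @return Symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
sample_distance_matrix <- function(abundance) {
  if (nrow(abundance) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(abundance))) stop("non-finite value in abundance table")
  D <- as.matrix(stats::dist(abundance, method = "euclidean"))
  dimnames(D) <- list(rownames(abundance), rownames(abundance))
  D
}

#' Default neighborhood size for the SNN graph
#'
#' The usual shared-nearest-neighbor heuristic: `round(sqrt(N))`, clipped to
#' `[2, N - 1]`.
#'
#' @param n Number of items.
#' @export
default_knn_k <- function(n) {
  max(2L, min(n - 1L, as.integer(round(sqrt(n)))))
}

#' k-nearest-neighbor sets from a distance matrix
#'
#' For each item, the k items with smallest distance plus the item itself.
#' Distance ties are broken by ascending item index so the construction is
#' deterministic.
#'
#' @param D Symmetric distance matrix.
#' @param k Neighborhood size, `1 <= k <= N - 1`.
#' @return Object of class `neighbor_sets`: list with `sets` (per item, a
#'   sorted integer vector of member indices, self included), `k`, `ids`.
#' @export
knn_neighbor_sets <- function(D, k) {
  n <- nrow(D)
  if (k < 1L || k > n - 1L) {
    stop("k must be in [1, N-1]; got k = ", k, ", N = ", n)
  }
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], others)]
    sets[[i]] <- sort(c(i, ord[seq_len(k)]))
  }
  structure(list(sets = sets, k = as.integer(k), ids = rownames(D)),
            class = "neighbor_sets")
}

#' Jaccard similarity of neighbor sets
#'
#' Shared-nearest-neighbor similarity: `J(i, j) = |N(i) n N(j)| /
#' |N(i) u N(j)|` over kNN sets (self included, so `J(i, i) = 1`).
#'
#' @param ns A [knn_neighbor_sets()] result.
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
jaccard_from_neighbors <- function(ns) {
  sets <- ns$sets
  n <- length(sets)
  J <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      J[i, j] <- J[j, i] <- inter / (length(sets[[i]]) + length(sets[[j]]) -
                                       inter)
    }
  }
  dimnames(J) <- list(ns$ids, ns$ids)
  J
}

#' Shared-nearest-neighbor Jaccard similarity from a distance matrix
#'
#' Convenience composition: [knn_neighbor_sets()] then
#' [jaccard_from_neighbors()].
#'
#' @param D Symmetric distance matrix.
#' @param k Neighborhood size; default [default_knn_k()].
#' @export
snn_similarity <- function(D, k = NULL) {
  if (is.null(k)) k <- default_knn_k(nrow(D))
  jaccard_from_neighbors(knn_neighbor_sets(D, k))
}

#' Dynamic time warping distance between two microbiota series
#'
#' Classic dynamic-programming DTW with the symmetric three-way step pattern:
#' local cost `c(t, u)` is the Euclidean distance between day-profile `t` of
#' `a` and day-profile `u` of `b`; the cumulative cost obeys
#' `D(t, u) = c(t, u) + min(D(t-1, u), D(t, u-1), D(t-1, u-1))` with
#' `D(1, 1) = c(1, 1)`. No window constraint; by default the returned value
#' is the raw cumulative cost `D(n, m)` (set `normalize = TRUE` to divide by
#' the optimal warping-path length). Repetition of elements along the path
#' is what absorbs missing sampling days, which is why the time-series
#' branch uses DTW at all.
#'
#' @param a,b [microbiota_series] objects (or plain numeric matrices with
#'   identical column sets, rows = time points).
#' @param normalize Divide by warping-path length? Default `FALSE`.
#' @param band Optional Sakoe-Chiba band half-width (in time steps);
#'   `Inf` (default) means unconstrained.
#' @return Nonnegative DTW distance; symmetric in its arguments.
#' @export
dtw_distance <- function(a, b, normalize = FALSE, band = Inf) {
  A <- if (inherits(a, "microbiota_series")) a$profiles else a
  B <- if (inherits(b, "microbiota_series")) b$profiles else b
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("series must be non-empty")
  if (ncol(A) != ncol(B) ||
      (!is.null(colnames(A)) && !is.null(colnames(B)) &&
       !identical(colnames(A), colnames(B)))) {
    stop("series have mismatched family universes")
  }
  n <- nrow(A); m <- nrow(B)
  cm <- matrix(0, n, m)
  for (i in seq_len(n)) {
    di <- sweep(B, 2L, A[i, ], "-")
    cm[i, ] <- sqrt(rowSums(di * di))
  }
  big <- Inf
  D <- matrix(big, n, m)
  L <- matrix(NA_integer_, n, m)   # optimal path length, for normalization
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (abs(i - j) > band) next
      if (i == 1L && j == 1L) {
        D[1L, 1L] <- cm[1L, 1L]; L[1L, 1L] <- 1L
        next
      }
      cand <- c(if (i > 1L) D[i - 1L, j] else big,
                if (i > 1L && j > 1L) D[i - 1L, j - 1L] else big,
                if (j > 1L) D[i, j - 1L] else big)
      lens <- c(if (i > 1L) L[i - 1L, j] else NA_integer_,
                if (i > 1L && j > 1L) L[i - 1L, j - 1L] else NA_integer_,
                if (j > 1L) L[i, j - 1L] else NA_integer_)
      w <- which.min(cand)
      D[i, j] <- cm[i, j] + cand[w]
      L[i, j] <- lens[w] + 1L
    }
  }
  if (!is.finite(D[n, m])) stop("band too narrow: no admissible warping path")
  if (normalize) D[n, m] / L[n, m] else D[n, m]
}

#' All-pairs DTW distance matrix over time series
#'
#' The time-series clustering branch: every pair of per-individual series is
#' compared by [dtw_distance()]; the result feeds the same kNN / Jaccard
#' construction as the sample-level branch.
#'
#' @param series_list List of [microbiota_series] (e.g. from
#'   [assemble_series()]).
#' @param ... Passed to [dtw_distance()] (`normalize`, `band`).
#' @return Symmetric distance matrix with series ids as dimnames.
#' @export
series_distance_matrix <- function(series_list, ...) {
  n <- length(series_list)
  if (n < 2L) stop("need at least 2 series")
  ids <- vapply(series_list, function(s)
    if (inherits(s, "microbiota_series")) s$series_id else NA_character_,
    character(1))
  if (anyNA(ids)) ids <- names(series_list)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- dtw_distance(series_list[[i]], series_list[[j]],
                                         ...)
    }
  }
  D
}
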