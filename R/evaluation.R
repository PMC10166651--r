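#' Normalized mutual information between two labelings
#'
#' `NMI = I(a; b) / norm(H(a), H(b))` from the label contingency table,
#' natural logarithms. The default normalization is the geometric mean
#' `sqrt(H(a) H(b))`; `max` and `arithmetic` are available because published
#' NMI values can shift slightly between variants. Degenerate conventions:
#' if both labelings have zero entropy (single cluster each) the score is 1;
#' if exactly one does, the score is 0.
#'
#' The score is invariant to permutation of cluster ids and symmetric in its
#' arguments; 1 means the partitions match exactly up to renaming.
#'
#' @param a,b Labelings over the same items in the same order (vectors,
#'   factors, or named integer vectors from the clusterers; when both are
#'   named the names must agree).
#' @param norm Normalization: `"sqrt"` (default), `"max"`, or
#'   `"arithmetic"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b, norm = c("sqrt", "max", "arithmetic")) {
  norm <- match.arg(norm)
  if (length(a) != length(b)) stop("labelings must cover the same items")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("labelings are over different item sets (names disagree)")
  }
  tab <- table(as.character(a), as.character(b))
  n <- sum(tab)
  pi_ <- rowSums(tab) / n
  pj_ <- colSums(tab) / n
  Ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  Hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  pij <- tab / n
  nz <- which(pij > 0, arr.ind = TRUE)
  I <- sum(pij[nz] * log(pij[nz] / (pi_[nz[, 1L]] * pj_[nz[, 2L]])))
  denom <- switch(norm,
                  sqrt = sqrt(Ha * Hb),
                  max = max(Ha, Hb),
                  arithmetic = (Ha + Hb) / 2)
  min(1, max(0, I / denom))
}

#' Assemble a clustering report row
#'
#' One row of the standard report: the three pairwise NMI values (community
#' detection vs Ward, each clusterer vs the true labels) and both cluster
#' counts, for one dataset slice and one approach.
#'
#' @param lab_ward,lab_com Labelings from [cut_by_height_gap()] and
#'   [community_detection()].
#' @param truth True labels for the same items (species, individual or site).
#' @param slice Dataset slice tag (`"total"` or a species name).
#' @param approach `"single"` or `"timeseries"`.
#' @param mode Label mode: `"species"`, `"individual"` or `"site"`.
#' @param norm NMI normalization, recorded in the result.
#' @return One-row `data.frame` with columns `slice`, `approach`, `mode`,
#'   `nmi_com_ward`, `nmi_ward_true`, `nmi_com_true`, `k_ward`, `k_com`;
#'   attribute `nmi_norm` records the normalization.
#' @export
build_report <- function(lab_ward, lab_com, truth, slice, approach,
                         mode = c("species", "individual", "site"),
                         norm = "sqrt") {
  mode <- match.arg(mode)
  if (is.null(truth) || !length(truth)) {
    stop("true labels for mode '", mode, "' are missing")
  }
  if (length(truth) != length(lab_ward)) {
    stop("true labels do not cover the clustered items")
  }
  out <- data.frame(
    slice = slice, approach = approach, mode = mode,
    nmi_com_ward = nmi(lab_com, lab_ward, norm = norm),
    nmi_ward_true = nmi(lab_ward, truth, norm = norm),
    nmi_com_true = nmi(lab_com, truth, norm = norm),
    k_ward = length(unique(lab_ward)),
    k_com = length(unique(lab_com)),
    stringsAsFactors = FALSE)
  attr(out, "nmi_norm") <- norm
  out
}
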