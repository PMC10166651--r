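#' LASSO selection of discriminating bacterial families
#'
#' Fits an L1-penalized multinomial logistic regression of the true labels
#' (species, individual, ...) on z-standardized family proportions. The L1
#' penalty performs variable selection by setting the coefficients of
#' irrelevant families exactly to zero; the families with any nonzero
#' coefficient at the chosen penalty are the "selected set" that best
#' discriminates the classes. The regularization strength is chosen on
#' glmnet's geometric lambda grid by stratified cross-validated multinomial
#' deviance at the CV minimum.
#'
#' @param abundance Samples x families proportion matrix.
#' @param labels True class label per sample (same order as rows); at least
#'   2 classes with at least 2 samples each.
#' @param nfolds Number of CV folds (default 5); folds are stratified by
#'   class and seeded for reproducibility.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @return Object of class `lasso_selection`: `coefficients` (families x
#'   classes matrix at the chosen penalty), `selected` (family ids with a
#'   nonzero coefficient in any class), `lambda`, `cv` (lambda / mean
#'   deviance / sd table, `NULL` if `lambda` was fixed), `classes`,
#'   `dropped` (constant families excluded before fitting), `seed`.
#' @export
lasso_select <- function(abundance, labels, nfolds = 5L, seed = 1L,
                         lambda = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(abundance)) {
    stop("labels must match abundance rows")
  }
  cls <- table(labels)
  if (length(cls) < 2L) stop("need at least 2 classes")
  if (any(cls < 2L)) {
    stop("class with < 2 samples: ", names(cls)[which(cls < 2L)[1L]])
  }
  sds <- apply(abundance, 2L, stats::sd)
  dropped <- colnames(abundance)[sds == 0]
  if (length(dropped)) {
    message("lasso_select: dropping ", length(dropped),
            " constant families")
  }
  X <- abundance[, sds > 0, drop = FALSE]
  Xz <- scale(X)
  y <- factor(labels)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Xz, y, family = "multinomial", alpha = 1,
                          standardize = FALSE)
    lam <- lambda
    cvtab <- NULL
  } else {
    foldid <- integer(length(y))
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    cv <- glmnet::cv.glmnet(Xz, y, family = "multinomial", alpha = 1,
                            standardize = FALSE, foldid = foldid,
                            type.measure = "deviance")
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    fit <- cv$glmnet.fit
    lam <- cv$lambda.min
    cvtab <- data.frame(lambda = cv$lambda, mean_deviance = cv$cvm,
                        sd_deviance = cv$cvsd)
  }
  cf <- stats::coef(fit, s = lam)
  coefmat <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1L, 1L]))
  colnames(coefmat) <- names(cf)
  selected <- rownames(coefmat)[rowSums(coefmat != 0) > 0]
  structure(list(coefficients = coefmat, selected = selected, lambda = lam,
                 cv = cvtab, classes = levels(y), dropped = dropped,
                 seed = seed, model = "multinomial"),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("<lasso_selection> multinomial L1, ", length(x$classes),
      " classes, lambda = ", format(x$lambda, digits = 4), "\n", sep = "")
  cat("  selected families (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Core and persistent taxa of a time series
#'
#' A *core* taxon of an individual's series is present (proportion above
#' `presence_threshold`) in every consecutive sample of the series; a
#' *persistent* taxon is present on at least two consecutive sampling days,
#' consecutive in calendar days (day index d and d+1 both sampled and both
#' positive), not merely in sample order. Every core taxon of a series with
#' at least two days is automatically persistent.
#'
#' @param series A [microbiota_series].
#' @param presence_threshold Proportion above which a family counts as
#'   present; default 0 (any nonzero abundance).
#' @return Character vector of family ids.
#' @export
core_taxa <- function(series, presence_threshold = 0) {
  pres <- series$profiles > presence_threshold
  colnames(series$profiles)[apply(pres, 2L, all)]
}

#' @rdname core_taxa
#' @export
persistent_taxa <- function(series, presence_threshold = 0) {
  days <- series$day_indices
  if (length(days) < 2L) {
    warning("series '", series$series_id,
            "' has a single day; no persistence is assessable")
    return(character())
  }
  pres <- series$profiles > presence_threshold
  pairs <- which(days[-1L] == days[-length(days)] + 1L)
  if (!length(pairs)) return(character())
  keep <- vapply(seq_len(ncol(pres)), function(f) {
    any(pres[pairs, f] & pres[pairs + 1L, f])
  }, logical(1))
  colnames(series$profiles)[keep]
}

#' Per-family abundance summary of a series
#'
#' Mean and sample standard deviation (n - 1 denominator) of the daily
#' percentage of each family over the series' sampled days, together with
#' core / persistent flags. Single-day series report sd 0 and are flagged.
#'
#' @param series A [microbiota_series].
#' @param presence_threshold Passed to [core_taxa()] / [persistent_taxa()].
#' @return `data.frame` with columns `series_id`, `family_id`, `mean_pct`,
#'   `sd_pct`, `core`, `persistent`, `single_day`.
#' @export
abundance_summary <- function(series, presence_threshold = 0) {
  pct <- series$profiles * 100
  nd <- nrow(pct)
  single <- nd < 2L
  sds <- if (single) rep(0, ncol(pct)) else apply(pct, 2L, stats::sd)
  core <- core_taxa(series, presence_threshold)
  pers <- if (single) character() else
    suppressWarnings(persistent_taxa(series, presence_threshold))
  data.frame(series_id = series$series_id,
             family_id = colnames(pct),
             mean_pct = colMeans(pct),
             sd_pct = sds,
             core = colnames(pct) %in% core,
             persistent = colnames(pct) %in% pers,
             single_day = single,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
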