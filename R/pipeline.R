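derive_min_clusters <- function(mode) if (mode == "species") 2L else 3L

truth_for <- function(metadata, sample_ids, mode) {
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  switch(mode,
         species = stats::setNames(md$species, sample_ids),
         individual = stats::setNames(md$individual, sample_ids),
         site = stats::setNames(md$site, sample_ids),
         stop("unknown label mode: ", mode))
}

series_truth_for <- function(series_list, mode) {
  field <- switch(mode, species = "species_label",
                  individual = "individual_id", site = "site_id",
                  stop("unknown label mode: ", mode))
  stats::setNames(vapply(series_list, `[[`, character(1), field),
                  vapply(series_list, `[[`, character(1), "series_id"))
}

#' Single-clustering branch
#'
#' Runs the per-sample branch of the pipeline: low-abundance filter,
#' relative abundances, pairwise Euclidean distances, kNN neighbor sets,
#' Jaccard similarity, then both clusterers (Ward's linkage with automatic
#' gap cut; greedy modularity community detection) and NMI scoring against
#' the true labels of the requested mode.
#'
#' @param counts Samples x families integer count matrix.
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param mode Label mode: `"species"`, `"individual"` or `"site"`.
#' @param slice Slice tag recorded in the report (default `"total"`).
#' @param knn_k Neighborhood size; default [default_knn_k()] of the item
#'   count.
#' @param min_clusters Minimum admissible cluster count; default 2 in
#'   species mode and 3 otherwise.
#' @param min_total Low-abundance filter threshold (sequences per family).
#' @param nmi_norm NMI normalization.
#' @return Object of class `microtrace_branch`: the report row plus
#'   labelings, dendrogram, similarity matrix and true labels.
#' @export
run_single_clustering <- function(counts, metadata,
                                  mode = c("species", "individual", "site"),
                                  slice = "total", knn_k = NULL,
                                  min_clusters = NULL, min_total = 10L,
                                  nmi_norm = "sqrt") {
  mode <- match.arg(mode)
  if (is.null(min_clusters)) min_clusters <- derive_min_clusters(mode)
  filt <- filter_low_abundance(counts, min_total)
  prop <- to_relative_abundance(filt)
  D <- sample_distance_matrix(prop)
  if (is.null(knn_k)) knn_k <- default_knn_k(nrow(D))
  J <- snn_similarity(D, knn_k)
  dend <- ward_linkage(similarity_to_dissimilarity(J))
  lab_ward <- cut_by_height_gap(dend, min_clusters)
  lab_com <- community_detection(J)
  truth <- truth_for(metadata, rownames(prop), mode)
  report <- build_report(lab_ward, lab_com, truth, slice, "single", mode,
                         nmi_norm)
  structure(list(report = report, labels = list(ward = lab_ward,
                                                community = lab_com),
                 truth = truth, dendrogram = dend, similarity = J,
                 knn_k = knn_k, min_clusters = min_clusters),
            class = "microtrace_branch")
}

#' Time-series clustering branch
#'
#' Runs the per-individual branch: filter, relative abundances, assembly of
#' per-individual time series, all-pairs dynamic time warping, kNN / Jaccard
#' similarity over series, then both clusterers and NMI scoring at the
#' series level (the true label of a series is its species, individual or
#' site).
#'
#' @inheritParams run_single_clustering
#' @param dtw_normalize Normalize DTW by warping-path length?
#' @param dtw_band Sakoe-Chiba band half-width (default unconstrained).
#' @return Object of class `microtrace_branch` (items are series).
#' @export
run_timeseries_clustering <- function(counts, metadata,
                                      mode = c("species", "individual",
                                               "site"),
                                      slice = "total", knn_k = NULL,
                                      min_clusters = NULL, min_total = 10L,
                                      nmi_norm = "sqrt",
                                      dtw_normalize = FALSE, dtw_band = Inf) {
  mode <- match.arg(mode)
  if (is.null(min_clusters)) min_clusters <- derive_min_clusters(mode)
  filt <- filter_low_abundance(counts, min_total)
  prop <- to_relative_abundance(filt)
  series <- assemble_series(prop, metadata)
  if (length(series) < 2L) stop("need at least 2 series")
  D <- series_distance_matrix(series, normalize = dtw_normalize,
                              band = dtw_band)
  if (is.null(knn_k)) knn_k <- default_knn_k(nrow(D))
  J <- snn_similarity(D, knn_k)
  dend <- ward_linkage(similarity_to_dissimilarity(J))
  lab_ward <- cut_by_height_gap(dend, min_clusters)
  lab_com <- community_detection(J)
  truth <- series_truth_for(series, mode)
  report <- build_report(lab_ward, lab_com, truth, slice, "timeseries",
                         mode, nmi_norm)
  structure(list(report = report, labels = list(ward = lab_ward,
                                                community = lab_com),
                 truth = truth, dendrogram = dend, similarity = J,
                 series = series, knn_k = knn_k,
                 min_clusters = min_clusters),
            class = "microtrace_branch")
}

#' @export
print.microtrace_branch <- function(x, ...) {
  r <- x$report
  cat("<microtrace_branch> ", r$approach, " clustering, ", r$mode,
      " mode, slice '", r$slice, "'\n", sep = "")
  print(r, row.names = FALSE)
  invisible(x)
}

#' Fit the full individual/species assignment protocol
#'
#' The main entry point. Runs both clustering branches (single-sample and
#' DTW time-series) on the total dataset in species mode and on each
#' per-species slice in individual mode, mirroring the full study protocol;
#' then identifies discriminating bacterial families by LASSO (species mode
#' on the whole dataset, individual mode within each species) and summarizes
#' core / persistent taxa and per-series abundance statistics.
#'
#' Per-species slices are re-filtered and re-normalized within the slice.
#'
#' @param counts Samples x families integer count matrix.
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param knn_k Neighborhood size override (default: `round(sqrt(N))` per
#'   branch).
#' @param min_total Low-abundance filter threshold.
#' @param nmi_norm NMI normalization (recorded in the report).
#' @param lasso_seed Seed for LASSO cross-validation folds.
#' @param presence_threshold Presence threshold for core/persistent taxa.
#' @param dtw_normalize,dtw_band DTW options (see [dtw_distance()]).
#' @return Object of class `microtrace` with elements `report` (one row per
#'   slice x approach), `branches`, `lasso` (species-mode selection plus one
#'   per-species individual-mode selection), `taxa` (per-series abundance
#'   summaries), `nmi_norm`, `call`.
#' @seealso [run_single_clustering()], [run_timeseries_clustering()],
#'   [lasso_select()], [generate_dataset()]
#' @examples
#' sim <- generate_dataset(generator_config(seed = 1))
#' fit <- microtrace(sim$counts, sim$metadata)
#' print(fit)
#' head(coef(fit, "species"))
#' @export
microtrace <- function(counts, metadata, knn_k = NULL, min_total = 10L,
                       nmi_norm = "sqrt", lasso_seed = 1L,
                       presence_threshold = 0, dtw_normalize = FALSE,
                       dtw_band = Inf) {
  metadata <- validate_metadata(metadata)
  species <- unique(metadata$species)
  branches <- list()
  reports <- list()
  run_both <- function(cts, md, mode, slice) {
    for (app in c("single", "timeseries")) {
      key <- paste(app, slice, sep = ".")
      branches[[key]] <<- if (app == "single") {
        run_single_clustering(cts, md, mode, slice, knn_k = knn_k,
                              min_total = min_total, nmi_norm = nmi_norm)
      } else {
        run_timeseries_clustering(cts, md, mode, slice, knn_k = knn_k,
                                  min_total = min_total,
                                  nmi_norm = nmi_norm,
                                  dtw_normalize = dtw_normalize,
                                  dtw_band = dtw_band)
      }
      reports[[key]] <<- branches[[key]]$report
    }
  }
  run_both(counts, metadata, "species", "total")
  for (sp in species) {
    md <- metadata[metadata$species == sp, , drop = FALSE]
    cts <- counts[md$sample_id, , drop = FALSE]
    run_both(cts, md, "individual", sp)
  }
  # attribution: species mode on the whole set, individual mode per species
  lasso <- list()
  filt <- filter_low_abundance(counts, min_total)
  prop <- to_relative_abundance(filt)
  if (length(species) >= 2L) {
    lasso$species <- lasso_select(
      prop, truth_for(metadata, rownames(prop), "species"),
      seed = lasso_seed)
  }
  for (sp in species) {
    md <- metadata[metadata$species == sp, , drop = FALSE]
    cts <- counts[md$sample_id, , drop = FALSE]
    sl_prop <- to_relative_abundance(filter_low_abundance(cts, min_total))
    lasso[[paste0("individual.", sp)]] <- lasso_select(
      sl_prop, truth_for(md, rownames(sl_prop), "individual"),
      seed = lasso_seed)
  }
  series <- assemble_series(prop, metadata)
  taxa <- do.call(rbind, lapply(series, abundance_summary,
                                presence_threshold = presence_threshold))
  rownames(taxa) <- NULL
  report <- do.call(rbind, unname(reports))
  rownames(report) <- NULL
  attr(report, "nmi_norm") <- nmi_norm
  structure(list(report = report, branches = branches, lasso = lasso,
                 taxa = taxa, series = series, nmi_norm = nmi_norm,
                 species = species, call = match.call()),
            class = "microtrace")
}

#' @export
print.microtrace <- function(x, digits = 2, ...) {
  cat("Individual/species assignment from longitudinal microbiota",
      "profiles\n")
  cat("NMI normalization:", x$nmi_norm, "\n\n")
  r <- x$report
  r$nmi_com_ward <- round(r$nmi_com_ward, digits)
  r$nmi_ward_true <- round(r$nmi_ward_true, digits)
  r$nmi_com_true <- round(r$nmi_com_true, digits)
  for (app in unique(r$approach)) {
    cat(switch(app, single = "Single clustering",
               timeseries = "Time series clustering"), "\n")
    print(r[r$approach == app,
            setdiff(names(r), "approach"), drop = FALSE],
          row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.microtrace <- function(object, ...) {
  structure(list(fit = object), class = "summary.microtrace")
}

#' @export
print.summary.microtrace <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("Discriminating families (LASSO):\n")
  for (nm in names(fit$lasso)) {
    cat("  ", nm, ": ",
        paste(fit$lasso[[nm]]$selected, collapse = ", "), "\n", sep = "")
  }
  core <- fit$taxa[fit$taxa$core, , drop = FALSE]
  core_all <- names(which(table(core$family_id) == length(fit$series)))
  cat("\nCore families in every series: ",
      if (length(core_all)) paste(core_all, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Extract LASSO coefficients from a fitted protocol
#'
#' @param object A [microtrace()] fit.
#' @param which Which selection: `"species"` or `"individual.<species>"`.
#' @param ... Ignored.
#' @return Families x classes coefficient matrix at the chosen penalty.
#' @export
coef.microtrace <- function(object, which = "species", ...) {
  if (!which %in% names(object$lasso)) {
    stop("no LASSO selection '", which, "'; available: ",
         paste(names(object$lasso), collapse = ", "))
  }
  object$lasso[[which]]$coefficients
}

#' Plot a dendrogram from a fitted protocol
#'
#' @param x A [microtrace()] fit.
#' @param branch Which branch to plot, e.g. `"timeseries.total"` (default)
#'   or `"single.<species>"`.
#' @param ... Passed to `plot.hclust`.
#' @export
plot.microtrace <- function(x, branch = "timeseries.total", ...) {
  if (!branch %in% names(x$branches)) {
    stop("no branch '", branch, "'; available: ",
         paste(names(x$branches), collapse = ", "))
  }
  dend <- x$branches[[branch]]$dendrogram
  graphics::plot(dend, main = branch, sub = "", xlab = "",
                 ylab = "ESS increase", ...)
  invisible(x)
}
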