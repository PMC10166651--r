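#' Read a taxon count table
#'
#' Reads a tab-separated feature table of nonnegative integer sequence counts
#' into a samples x families integer matrix. Amplicon pipelines usually export
#' tables with taxa as rows; set `taxa_as_rows = TRUE` to accept that
#' orientation, the table is transposed on read.
#'
#' @param path Path to a TSV file with a header row; the first column holds
#'   sample ids (or taxon ids when `taxa_as_rows = TRUE`).
#' @param taxa_as_rows Logical; `TRUE` when rows are taxa and columns samples.
#' @return Integer matrix (samples x families) with sample ids as row names
#'   and family ids as column names, input ordering preserved.
#' @seealso [write_count_table()], [filter_low_abundance()],
#'   [to_relative_abundance()]
#' @export
read_count_table <- function(path, taxa_as_rows = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  if (ncol(raw) < 2L) {
    stop("count table needs an id column plus at least one data column")
  }
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (taxa_as_rows) mat <- t(mat)
  validate_count_matrix(mat)
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count table to TSV
#'
#' @param counts Samples x families integer matrix as returned by
#'   [read_count_table()].
#' @param path Output path; tab-delimited UTF-8, header row of family ids,
#'   first column `sample_id`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

validate_count_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("count table must carry sample and family ids")
  }
  dup_s <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_s)) stop("duplicate sample id: ", dup_s[1L])
  dup_f <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_f)) stop("duplicate family id: ", dup_f[1L])
  if (!is.numeric(mat)) stop("count table cells must be numeric")
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count (non-integer or negative) at sample '%s', family '%s'",
      rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  invisible(mat)
}

#' Read sample metadata
#'
#' Metadata link each fecal sample to its host: species, individual, site
#' (zoo), time series and day index. One individual may contribute more than
#' one time series, so the series id -- not the individual -- is the grouping
#' unit for [assemble_series()].
#'
#' @param path TSV with columns `sample_id`, `species`, `individual`, `site`,
#'   `series`, `day` (integer day index >= 1, strictly ordered within series).
#' @return A `data.frame` with those six columns, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata Metadata data frame to write.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_metadata <- function(df) {
  required <- c("sample_id", "species", "individual", "site", "series", "day")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id in metadata: ", dup[1L])
  if (!is.numeric(df$day) || any(is.na(df$day)) || any(df$day != round(df$day))) {
    stop("metadata 'day' must be integer")
  }
  if (any(df$day < 1L)) stop("metadata 'day' must be >= 1")
  df$day <- as.integer(df$day)
  key <- paste(df$series, df$day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (series, day) in metadata: ('%s', %d)",
                 df$series[dup[1L]], df$day[dup[1L]]))
  }
  for (cn in c("species", "individual", "site", "series")) {
    df[[cn]] <- as.character(df[[cn]])
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Remove low-abundance families
#'
#' Drops every bacterial family whose total count over the whole dataset is
#' below `min_total` sequences (default 10, the usual low-abundance cutoff
#' for amplicon feature tables). The filter is applied to dataset-wide column
#' totals, so it is idempotent; samples are never removed.
#'
#' @param counts Samples x families integer matrix.
#' @param min_total Minimum dataset-wide sequence count for a family to be
#'   retained; families with column sum `>= min_total` are kept.
#' @return Filtered count matrix with the same samples.
#' @export
filter_low_abundance <- function(counts, min_total = 10L) {
  validate_count_matrix(counts)
  stopifnot(min_total >= 0)
  keep <- colSums(counts) >= min_total
  if (!any(keep)) {
    stop("filter removed every family; lower min_total (currently ",
         min_total, ")")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message("filter_low_abundance: removed ", n_removed, " of ",
            ncol(counts), " families (< ", min_total, " sequences)")
  }
  counts[, keep, drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' @param counts Samples x families matrix of nonnegative counts; every
#'   sample must have a positive total.
#' @return Numeric matrix of per-sample proportions; each row sums to 1.
#' @export
to_relative_abundance <- function(counts) {
  validate_count_matrix(counts)
  totals <- rowSums(counts)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("sample '", rownames(counts)[zero[1L]], "' has zero total count")
  }
  sweep(counts, 1L, totals, "/")
}

#' Assemble per-individual time series
#'
#' Groups the samples of an abundance table into one [microbiota_series] per
#' time series id, ordered by day index. Missing days are simply absent
#' (series may be shorter than the collection window); downstream dynamic
#' time warping absorbs the unequal lengths.
#'
#' @param abundance Samples x families proportion matrix
#'   (see [to_relative_abundance()]).
#' @param metadata Metadata data frame (see [read_metadata()]); every sample
#'   in `abundance` must have exactly one record.
#' @return Named list of `microbiota_series` objects, one per series id that
#'   has at least one sample in the table.
#' @export
assemble_series <- function(abundance, metadata) {
  metadata <- validate_metadata(metadata)
  samples <- rownames(abundance)
  unknown <- setdiff(samples, metadata$sample_id)
  if (length(unknown)) {
    stop("sample without metadata record: ", unknown[1L])
  }
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  empty <- setdiff(unique(metadata$series), unique(md$series))
  if (length(empty)) {
    warning("series with zero samples in table omitted: ",
            paste(empty, collapse = ", "))
  }
  out <- list()
  for (sid in unique(md$series)) {
    rows <- which(md$series == sid)
    rows <- rows[order(md$day[rows])]
    out[[sid]] <- microbiota_series(
      series_id = sid,
      individual_id = md$individual[rows[1L]],
      species_label = md$species[rows[1L]],
      site_id = md$site[rows[1L]],
      day_indices = md$day[rows],
      profiles = abundance[rows, , drop = FALSE])
  }
  out
}

#' One individual's microbiota time series
#'
#' @param series_id,individual_id,species_label,site_id Identifiers.
#' @param day_indices Strictly increasing integer day indices.
#' @param profiles Days x families matrix of proportions, rows summing to 1.
#' @return Object of class `microbiota_series`.
#' @export
microbiota_series <- function(series_id, individual_id, species_label,
                              site_id, day_indices, profiles) {
  if (length(day_indices) != nrow(profiles)) {
    stop("day_indices length must match profile rows")
  }
  if (is.unsorted(day_indices, strictly = TRUE)) {
    stop("day_indices must be strictly increasing")
  }
  sums <- rowSums(profiles)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("series profiles must each sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  structure(
    list(series_id = as.character(series_id),
         individual_id = as.character(individual_id),
         species_label = as.character(species_label),
         site_id = as.character(site_id),
         day_indices = as.integer(day_indices),
         profiles = profiles),
    class = "microbiota_series")
}

#' @export
print.microbiota_series <- function(x, ...) {
  cat("<microbiota_series> ", x$series_id, ": ", x$species_label, " / ",
      x$individual_id, " @ ", x$site_id, "\n", sep = "")
  cat("  days sampled: ", paste(x$day_indices, collapse = ", "),
      "  (", ncol(x$profiles), " families)\n", sep = "")
  invisible(x)
}
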