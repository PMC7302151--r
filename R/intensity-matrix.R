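#' Construct an intensity matrix
#'
#' The shared container for quantitative omics tables: an entity-by-sample
#' grid of non-negative intensities (LFQ for protein, FPKM for transcript)
#' with per-sample design metadata. Missing measurements are stored as `NA`,
#' which is distinct from an observed zero; on the raw scale a zero in a
#' MaxQuant LFQ column means "not quantified" and is converted to `NA` at
#' read time.
#'
#' @param values numeric matrix, entities in rows, samples in columns.
#'   Rownames are the entity identifiers and must be unique.
#' @param samples data.frame describing the columns, one row per sample, with
#'   columns `condition` (`"Nminus"` or `"Nplus"`), `timepoint` (hours,
#'   positive) and `replicate` (integer >= 1). Row order matches the column
#'   order of `values`.
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `IntensityMatrix`: a list with elements
#'   `values`, `samples` and `scale`.
#' @export
intensity_matrix <- function(values, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("`values` must carry entity ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated entity id in intensity matrix", call. = FALSE)
  }
  samples <- validate_sample_frame(samples)
  if (nrow(samples) != ncol(values)) {
    stop("sample metadata rows (", nrow(samples),
         ") do not match value columns (", ncol(values), ")", call. = FALSE)
  }
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, samples = samples, scale = scale),
    class = "IntensityMatrix"
  )
}

validate_sample_frame <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("condition", "timepoint", "replicate")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(samples$condition), c("Nminus", "Nplus"))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected 'Nminus'/'Nplus')", call. = FALSE)
  }
  if (any(!is.finite(samples$timepoint)) || any(samples$timepoint <= 0)) {
    stop("timepoints must be positive numbers (hours)", call. = FALSE)
  }
  if (any(samples$replicate < 1)) {
    stop("replicate indices start at 1", call. = FALSE)
  }
  samples$replicate <- as.integer(samples$replicate)
  rownames(samples) <- NULL
  samples
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat("IntensityMatrix (", x$scale, " scale): ",
      nrow(x$values), " entities x ", ncol(x$values), " samples; ",
      n_missing, " missing cells\n", sep = "")
  tp <- sort(unique(x$samples$timepoint))
  cat("  timepoints (h): ", paste(tp, collapse = ", "), "\n", sep = "")
  cat("  conditions: ",
      paste(sprintf("%s (n=%d)", names(table(x$samples$condition)),
                    as.integer(table(x$samples$condition))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

#' Construct a fold-change table
#'
#' Entity-by-timepoint log2 ratios between the nitrogen-deplete and replete
#' conditions: log2LFQ(N-/N+) for the protein layer ("LogetP") or
#' log2FPKM(N-/N+) for the transcript layer ("LogetT").
#'
#' @param values numeric matrix, entities x timepoints, rownames = entity ids.
#' @param timepoints numeric vector of hours, strictly increasing, one per
#'   column of `values`.
#' @param layer `"protein"` or `"transcript"`.
#' @return An object of class `FoldChangeTable`.
#' @export
fold_change_table <- function(values, timepoints, layer = c("protein", "transcript")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || is.null(rownames(values))) {
    stop("`values` must be a matrix with entity rownames", call. = FALSE)
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values)) {
    stop("one timepoint per column required", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  colnames(values) <- paste0("t", timepoints)
  structure(
    list(values = values, timepoints = timepoints, layer = layer),
    class = "FoldChangeTable"
  )
}

#' @export
print.FoldChangeTable <- function(x, ...) {
  cat("FoldChangeTable [", x$layer, "]: ", nrow(x$values), " entities x ",
      length(x$timepoints), " timepoints (",
      paste(x$timepoints, collapse = ", "), " h)\n", sep = "")
  invisible(x)
}

#' @export
dim.FoldChangeTable <- function(x) dim(x$values)
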