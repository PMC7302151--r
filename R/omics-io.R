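#' Build a sample map
#'
#' A sample map ties on-disk column names to the experimental design. All
#' readers take one, so any column naming convention (MaxQuant versions
#' differ, GEO matrices differ) is handled by configuration instead of
#' guessing.
#'
#' @param column character vector of column names as they appear in the file
#'   (for proteinGroups tables, the full header, e.g.
#'   `"LFQ intensity Nminus_3h_1"`).
#' @param condition `"Nminus"`/`"Nplus"` per column.
#' @param timepoint hours per column.
#' @param replicate replicate index per column.
#' @return data.frame with one row per quantified sample column.
#' @export
sample_map <- function(column, condition, timepoint, replicate) {
  map <- data.frame(
    column = as.character(column),
    condition = as.character(condition),
    timepoint = as.numeric(timepoint),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$column)) {
    stop("duplicated file column in sample map", call. = FALSE)
  }
  validate_sample_frame(map[c("condition", "timepoint", "replicate")])
  map
}

read_tsv_raw <- function(path, skip_bang = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (skip_bang) lines <- lines[!startsWith(lines, "!")]
  if (!length(lines)) {
    stop("empty table: ", path, call. = FALSE)
  }
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a MaxQuant proteinGroups-style table
#'
#' Reads the tab-separated protein quantification output of a MaxQuant-style
#' search into an [intensity_matrix()]. Rows flagged `"+"` in the optional
#' `Reverse` or `Potential contaminant` columns are dropped before anything
#' is counted, and zeros in LFQ columns become missing values (the MaxLFQ
#' convention: an LFQ intensity of 0 means the protein was not quantified in
#' that run, not that it is absent at zero abundance).
#'
#' @param path path to the tab-separated file.
#' @param map a [sample_map()] whose `column` entries name the LFQ intensity
#'   columns to extract; the returned sample order follows the map, not the
#'   file.
#' @param id_col name of the identifier column (default `"Protein IDs"`).
#' @return A raw-scale [intensity_matrix()].
#' @export
read_protein_groups <- function(path, map, id_col = "Protein IDs") {
  tab <- read_tsv_raw(path)
  if (!id_col %in% names(tab)) {
    stop("format error: identifier column '", id_col, "' not found in ",
         path, call. = FALSE)
  }
  missing_cols <- setdiff(map$column, names(tab))
  if (length(missing_cols)) {
    stop("configuration error: sample map column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (flag_col in c("Reverse", "Potential contaminant")) {
    if (flag_col %in% names(tab)) {
      tab <- tab[trimws(tab[[flag_col]]) != "+", , drop = FALSE]
    }
  }
  ids <- tab[[id_col]]
  if (anyDuplicated(ids)) {
    stop("format error: duplicated entity id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  values <- as_numeric_grid(tab[map$column], path)
  values[values == 0] <- NA_real_   # MaxLFQ zero-means-unquantified
  rownames(values) <- ids
  colnames(values) <- map$column
  intensity_matrix(values, map[c("condition", "timepoint", "replicate")],
                   scale = "raw")
}

as_numeric_grid <- function(df, path) {
  out <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df))
  for (j in seq_along(df)) {
    cell <- trimws(df[[j]])
    cell[cell %in% c("", "NA", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop("format error: non-numeric cell '", cell[bad[1]], "' at row ",
           bad[1], ", column '", names(df)[j], "' of ", path, call. = FALSE)
    }
    out[, j] <- num
  }
  out
}

#' Read an FPKM gene-by-sample matrix
#'
#' Accepts a plain tab-separated gene x sample table or a GEO
#' series-matrix-like layout (header lines starting with `!` are skipped).
#' The first column is taken as the gene identifier.
#'
#' @inheritParams read_protein_groups
#' @param geo_dialect if `TRUE`, lines beginning with `!` are ignored.
#' @return A raw-scale [intensity_matrix()] of FPKM values.
#' @export
read_fpkm_matrix <- function(path, map, geo_dialect = FALSE) {
  tab <- read_tsv_raw(path, skip_bang = geo_dialect)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop("format error: duplicated gene id(s) in ", path, call. = FALSE)
  }
  missing_cols <- setdiff(map$column, names(tab))
  if (length(missing_cols)) {
    stop("configuration error: sample map column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  values <- as_numeric_grid(tab[map$column], path)
  rownames(values) <- ids
  colnames(values) <- map$column
  message("read_fpkm_matrix: ", nrow(values), " gene rows from ", path)
  intensity_matrix(values, map[c("condition", "timepoint", "replicate")],
                   scale = "raw")
}

#' Default twelve-category functional vocabulary
#'
#' The categories used to summarise cluster membership. Supplied as a default
#' only; any vocabulary can be passed to [read_annotations()].
#' @return character vector of twelve category names.
#' @export
default_category_vocabulary <- function() {
  c("photosynthesis", "carbon metabolism", "protein synthesis",
    "gene expression", "energy", "transport", "lipid metabolism",
    "nitrogen metabolism", "cell structure", "chromatin",
    "other metabolism", "unknown function")
}

#' Read an entity annotation table
#'
#' Tab-separated table with columns `entity_id`, `category` and optionally
#' one column per localization-prediction tool (e.g. `signalp`, `chlorop`,
#' `targetp`). Categories outside the vocabulary are mapped to `"unknown"`
#' with a warning; on duplicated ids the last record wins.
#'
#' @param path path to the annotation TSV.
#' @param vocabulary allowed category names.
#' @return data.frame with `entity_id`, `category`, any tool columns, and a
#'   `consensus` column initialised to `NA` (fill with
#'   [consensus_localization()]).
#' @export
read_annotations <- function(path, vocabulary = default_category_vocabulary()) {
  tab <- tryCatch(read_tsv_raw(path), error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(data.frame(entity_id = character(), category = character(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  if (!all(c("entity_id", "category") %in% names(tab))) {
    stop("format error: annotation table needs 'entity_id' and 'category' columns",
         call. = FALSE)
  }
  if (anyDuplicated(tab$entity_id)) {
    warning("duplicated annotation id(s); keeping the last record",
            call. = FALSE)
    tab <- tab[!duplicated(tab$entity_id, fromLast = TRUE), , drop = FALSE]
  }
  outside <- !(tab$category %in% vocabulary)
  if (any(outside)) {
    warning(sum(outside), " annotation(s) outside the category vocabulary ",
            "mapped to 'unknown'", call. = FALSE)
    tab$category[outside] <- "unknown"
  }
  tab$consensus <- NA_character_
  rownames(tab) <- NULL
  tab
}

#' Write a result table as TSV
#'
#' Common writer for all downstream tables: tab-separated, UTF-8, missing
#' cells rendered `"NA"`, numeric cells at a configurable precision
#' (`digits = NA` keeps full precision so write/read round-trips are exact).
#'
#' @param x data.frame or matrix (matrices are written with a leading
#'   `entity_id` column from their rownames).
#' @param path output path.
#' @param digits significant digits for numeric columns, or `NA` for full
#'   precision.
#' @export
write_results_table <- function(x, path, digits = NA) {
  if (is.matrix(x)) {
    x <- data.frame(entity_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = digits)
  }
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write / re-read an intensity matrix
#'
#' `write_intensity_matrix()` stores the value grid as TSV with the on-disk
#' column names taken from the sample metadata; reading it back with the same
#' sample map reproduces the object exactly (ids, order, values and missing
#' pattern).
#'
#' @param x an [intensity_matrix()].
#' @param path output path.
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "IntensityMatrix"))
  vals <- x$values
  colnames(vals) <- sample_labels(x$samples)
  write_results_table(vals, path, digits = NA)
}

#' @rdname write_intensity_matrix
#' @param map a [sample_map()]; `column` entries must equal the labels
#'   produced by `write_intensity_matrix()` for the stored design.
#' @param scale scale to stamp on the re-read matrix.
#' @export
read_intensity_matrix <- function(path, map, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  tab <- read_tsv_raw(path)
  missing_cols <- setdiff(map$column, names(tab))
  if (length(missing_cols)) {
    stop("configuration error: sample map column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  values <- as_numeric_grid(tab[map$column], path)
  rownames(values) <- tab[[1]]
  colnames(values) <- map$column
  intensity_matrix(values, map[c("condition", "timepoint", "replicate")],
                   scale = scale)
}

sample_labels <- function(samples) {
  sprintf("%s_%gh_%d", samples$condition, samples$timepoint,
          samples$replicate)
}

#' Sample map matching write_intensity_matrix() labels
#'
#' Convenience constructor used for round-trips and by the synthetic
#' generator: builds the [sample_map()] whose column names are the canonical
#' `<condition>_<timepoint>h_<replicate>` labels.
#'
#' @param samples sample metadata data.frame (`condition`, `timepoint`,
#'   `replicate`).
#' @return a [sample_map()].
#' @export
canonical_sample_map <- function(samples) {
  sample_map(sample_labels(samples), samples$condition, samples$timepoint,
             samples$replicate)
}
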