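#' Spearman correlation distance between fold-change profiles
#'
#' `d(i, j) = 1 - rho_spearman(profile_i, profile_j)`, in `[0, 2]`, with
#' average ranking for ties. A constant profile has no defined rank
#' correlation; it is placed at distance 1 from every other entity and
#' listed in the `flagged` attribute.
#'
#' @param fc a [fold_change_table()] with >= 2 entities and >= 3 timepoints.
#' @return symmetric distance matrix with zero diagonal; constant-profile
#'   ids in `attr(, "flagged")`.
#' @export
spearman_distance_matrix <- function(fc) {
  stopifnot(inherits(fc, "FoldChangeTable"))
  vals <- fc$values
  if (nrow(vals) < 2 || ncol(vals) < 3) {
    stop("need >= 2 entities and >= 3 timepoints", call. = FALSE)
  }
  constant <- apply(vals, 1, function(r) length(unique(r)) == 1)
  rho <- suppressWarnings(stats::cor(t(vals), method = "spearman"))
  d <- 1 - rho
  d[constant, ] <- 1
  d[, constant] <- 1
  diag(d) <- 0
  if (any(constant)) {
    warning(sum(constant), " constant profile(s) set to distance 1 from all others",
            call. = FALSE)
  }
  attr(d, "flagged") <- rownames(vals)[constant]
  d
}

#' Cut an agglomerative dendrogram into k clusters
#'
#' Average-linkage hierarchical clustering (configurable) of a precomputed
#' distance matrix, cut to exactly `k` clusters.
#'
#' @param dist_mat symmetric distance matrix with zero diagonal.
#' @param k number of clusters; the study's row clustering uses k = 8.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return named integer vector of cluster indices in `1..k`.
#' @export
hierarchical_cut <- function(dist_mat, k = 8, linkage = "average") {
  n <- nrow(dist_mat)
  if (k > n) stop("domain error: k exceeds the number of entities", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dist_mat), method = linkage)
  stats::cutree(hc, k = k)
}

#' Per-cluster mean fold-change profiles
#'
#' @param fc a [fold_change_table()].
#' @param assignments named integer vector covering the table's entities.
#' @return data.frame with `cluster`, `size`, and one mean column per
#'   timepoint.
#' @export
cluster_means <- function(fc, assignments) {
  stopifnot(inherits(fc, "FoldChangeTable"))
  ids <- rownames(fc$values)
  if (!all(ids %in% names(assignments))) {
    stop("assignments must cover every entity in the table", call. = FALSE)
  }
  cl <- assignments[ids]
  out <- lapply(sort(unique(cl)), function(j) {
    sub <- fc$values[cl == j, , drop = FALSE]
    cbind(data.frame(cluster = j, size = nrow(sub)),
          as.data.frame(t(colMeans(sub))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group timepoint columns into phases
#'
#' Euclidean hierarchical clustering of the per-timepoint fold-change
#' vectors (the heatmap's columns), cut into `n_phases` groups. In the study
#' design this separates an early, a mid and a late-starvation phase, with
#' the 10-day samples standing apart from everything earlier.
#'
#' @param fc a [fold_change_table()].
#' @param n_phases number of column groups (default 3).
#' @param linkage linkage method.
#' @return data.frame with `timepoint` and `phase` (group index).
#' @export
column_phase_grouping <- function(fc, n_phases = 3, linkage = "average") {
  stopifnot(inherits(fc, "FoldChangeTable"))
  if (n_phases > length(fc$timepoints)) {
    stop("domain error: more phases than timepoints", call. = FALSE)
  }
  d <- stats::dist(t(fc$values), method = "euclidean")
  grp <- stats::cutree(stats::hclust(d, method = linkage), k = n_phases)
  data.frame(timepoint = fc$timepoints, phase = unname(grp))
}

#' PCA of samples from an intensity matrix
#'
#' Samples are the observations, entities the features; features are
#' centered but not scaled to unit variance (log-scale LFQ magnitudes carry
#' signal).
#'
#' @param x a log2-scale, imputed [intensity_matrix()] with >= 3 samples.
#' @return list with `scores` (samples x components), `variance_explained`
#'   (fractions, non-increasing) and the sample metadata.
#' @export
pca_samples <- function(x) {
  stopifnot(inherits(x, "IntensityMatrix"))
  if (ncol(x$values) < 3) stop("need >= 3 samples for PCA", call. = FALSE)
  if (anyNA(x$values)) stop("impute before PCA", call. = FALSE)
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, samples = x$samples)
}
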