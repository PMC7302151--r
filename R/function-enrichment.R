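#' Most frequent functional categories per cluster
#'
#' Counts the functional category of every assigned entity within each
#' cluster and ranks categories by descending count (ties broken
#' alphabetically). The top `n_top` categories — the study uses five,
#' unknown-function genes included — are flagged as the cluster's primary
#' functions.
#'
#' @param assignments named integer vector (entity -> cluster).
#' @param annotations data.frame from [read_annotations()]; every assigned
#'   entity must appear (category `"unknown"` is allowed and counted).
#' @param n_top how many top categories to flag per cluster.
#' @return data.frame with `cluster`, `category`, `count`, `rank`, `top`.
#' @export
top_categories <- function(assignments, annotations, n_top = 5) {
  cat_of <- stats::setNames(annotations$category, annotations$entity_id)
  ids <- names(assignments)
  missing <- setdiff(ids, names(cat_of))
  if (length(missing)) {
    stop("unannotated entities in assignments: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ..." else "", call. = FALSE)
  }
  out <- lapply(sort(unique(assignments)), function(j) {
    cats <- cat_of[ids[assignments == j]]
    tab <- table(cats)
    df <- data.frame(cluster = j, category = names(tab),
                     count = as.integer(tab), stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$category), ]
    df$rank <- seq_len(nrow(df))
    df$top <- df$rank <= n_top
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-category transcript-minus-protein fold-change difference
#'
#' For every functional category and every timepoint shared by the two
#' layers, aggregates the transcript fold changes (LogetT) over the
#' category's genes detected on the transcript layer and the protein fold
#' changes (LogetP) over its genes detected on the protein layer, and
#' reports their difference `delta = LogetT - LogetP`. Membership is
#' per-layer by default (each layer's own detected set); `intersect_members`
#' restricts both layers to genes detected in both.
#'
#' @param fc_t transcript-layer [fold_change_table()].
#' @param fc_p protein-layer [fold_change_table()].
#' @param annotations data.frame from [read_annotations()].
#' @param stat aggregation over category members, `"mean"` or `"median"`.
#' @param intersect_members use only genes present in both layers.
#' @return data.frame in long format: `category`, `timepoint`, `mean_t`,
#'   `mean_p`, `delta`, `n_t`, `n_p`. Categories with no members in either
#'   layer are omitted with a warning.
#' @export
category_delta <- function(fc_t, fc_p, annotations,
                           stat = c("mean", "median"),
                           intersect_members = FALSE) {
  stopifnot(inherits(fc_t, "FoldChangeTable"), inherits(fc_p, "FoldChangeTable"))
  stat <- match.arg(stat)
  agg <- if (stat == "mean") mean else stats::median
  shared_tp <- sort(intersect(fc_t$timepoints, fc_p$timepoints))
  if (!length(shared_tp)) stop("no shared timepoints", call. = FALSE)
  cat_of <- stats::setNames(annotations$category, annotations$entity_id)
  pool <- if (intersect_members) {
    intersect(rownames(fc_t$values), rownames(fc_p$values))
  } else NULL
  rows <- list()
  skipped <- character(0)
  for (cat in sort(unique(annotations$category))) {
    members <- annotations$entity_id[annotations$category == cat]
    mt <- intersect(members, rownames(fc_t$values))
    mp <- intersect(members, rownames(fc_p$values))
    if (!is.null(pool)) {
      mt <- intersect(mt, pool); mp <- intersect(mp, pool)
    }
    if (!length(mt) && !length(mp)) {
      skipped <- c(skipped, cat)
      next
    }
    for (tp in shared_tp) {
      vt <- if (length(mt)) agg(fc_t$values[mt, match(tp, fc_t$timepoints)]) else NA_real_
      vp <- if (length(mp)) agg(fc_p$values[mp, match(tp, fc_p$timepoints)]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, timepoint = tp, mean_t = vt, mean_p = vp,
        delta = vt - vp, n_t = length(mt), n_p = length(mp),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("categories with no members in either layer omitted: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
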