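#' Log2-transform an intensity matrix
#'
#' @param x a raw-scale [intensity_matrix()]; every present value must be
#'   strictly positive (zeros should already have been converted to missing
#'   by the readers).
#' @return the matrix on the log2 scale; missing cells stay missing.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "IntensityMatrix"))
  if (x$scale != "raw") stop("matrix is already on the log2 scale", call. = FALSE)
  bad <- which(x$values <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(x$values))
    stop("domain error: non-positive intensity at entity '",
         rownames(x$values)[rc[1]], "', sample ", rc[2], call. = FALSE)
  }
  out <- x
  out$values <- log2(x$values)
  out$scale <- "log2"
  out
}

#' Filter entities by minimum quantification
#'
#' Removes entities quantified too sparsely to compare between conditions.
#' Two counting semantics are provided:
#' \describe{
#'   \item{`"sample"`}{an entity is kept iff, within each condition
#'     separately, the number of non-missing samples is at least
#'     `ceiling(min_fraction * samples in that condition)`.}
#'   \item{`"timepoint"`}{a timepoint counts as quantified when at least one
#'     replicate is non-missing; the entity is kept iff quantified timepoints
#'     reach `ceiling(min_fraction * timepoints)` in each condition.}
#' }
#' The default reproduces the half-of-samples rule used to reduce the
#' identified proteome to the comparable core set.
#'
#' @param x an [intensity_matrix()].
#' @param min_fraction fraction in (0, 1]; default 0.5.
#' @param mode `"sample"` or `"timepoint"`.
#' @return list with `matrix` (the filtered [intensity_matrix()]) and
#'   `report` (kept/removed ids, mode, min_fraction).
#' @export
filter_min_quantified <- function(x, min_fraction = 0.5,
                                  mode = c("sample", "timepoint")) {
  stopifnot(inherits(x, "IntensityMatrix"))
  mode <- match.arg(mode)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  conds <- c("Nminus", "Nplus")
  if (!all(conds %in% x$samples$condition)) {
    stop("configuration error: both conditions must have samples", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(x$values))
  for (cond in conds) {
    in_cond <- x$samples$condition == cond
    present <- !is.na(x$values[, in_cond, drop = FALSE])
    if (mode == "sample") {
      need <- ceiling(min_fraction * sum(in_cond))
      keep <- keep & (rowSums(present) >= need)
    } else {
      tps <- x$samples$timepoint[in_cond]
      quantified <- vapply(unique(tps), function(tp) {
        rowSums(present[, tps == tp, drop = FALSE]) >= 1
      }, logical(nrow(x$values)))
      if (is.null(dim(quantified))) quantified <- matrix(quantified, nrow = 1)
      need <- ceiling(min_fraction * length(unique(tps)))
      keep <- keep & (rowSums(quantified) >= need)
    }
  }
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  list(
    matrix = out,
    report = list(
      kept_ids = rownames(x$values)[keep],
      removed_ids = rownames(x$values)[!keep],
      mode = mode,
      min_fraction = min_fraction
    )
  )
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Perseus-style imputation for left-censored (MNAR) label-free data: each
#' missing cell in sample column j is replaced by a draw from
#' `Normal(mean_j - down_shift * sd_j, (width * sd_j)^2)`, where `mean_j` and
#' `sd_j` are computed over the column's present values. The defaults
#' (width 0.3, down-shift 1.8, in column-SD units) are the Perseus defaults
#' for simulating abundances around the detection limit.
#'
#' One RNG stream seeded from `seed` is consumed column-by-column in sample
#' order, so results are bit-reproducible and independent of entity order.
#'
#' @param x a log2-scale [intensity_matrix()]; every column needs >= 2
#'   present values (the column SD must be defined).
#' @param width spread of the imputation distribution, as a fraction of the
#'   column SD.
#' @param down_shift centre offset below the column mean, in column-SD units.
#' @param seed integer seed.
#' @return the matrix with no missing cells; present values untouched.
#' @export
impute_downshifted_normal <- function(x, width = 0.3, down_shift = 1.8, seed = 1L) {
  stopifnot(inherits(x, "IntensityMatrix"))
  if (x$scale != "log2") stop("impute on the log2 scale", call. = FALSE)
  stopifnot(width > 0, down_shift >= 0)
  vals <- x$values
  n_present <- colSums(!is.na(vals))
  if (any(n_present < 2)) {
    stop("column ", which(n_present < 2)[1],
         " has fewer than 2 present values; sd undefined", call. = FALSE)
  }
  rng <- local_rng(seed)
  for (j in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, j]))
    mu <- mean(vals[, j], na.rm = TRUE)
    sdev <- stats::sd(vals[, j], na.rm = TRUE)
    if (length(miss)) {
      vals[miss, j] <- rng$rnorm(length(miss),
                                 mean = mu - down_shift * sdev,
                                 sd = width * sdev)
    }
  }
  out <- x
  out$values <- vals
  out
}

# Small closure giving a private RNG stream that never disturbs (and is never
# disturbed by) the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    sample_int = function(n, size, replace = FALSE) draw(sample.int, n, size, replace)
  )
}

#' Replicate-mean log2 fold changes between conditions
#'
#' For every entity and timepoint shared by both conditions, the fold change
#' is the mean over replicates of the log2 value under N- minus the mean
#' under N+ (i.e. log2 of the intensity ratio, "LogetP" for the protein
#' layer, "LogetT" for the transcript layer). Timepoints present in only one
#' condition are excluded with a warning.
#'
#' @param x a log2-scale, imputed [intensity_matrix()].
#' @param layer `"protein"` or `"transcript"`.
#' @return a [fold_change_table()].
#' @export
fold_change <- function(x, layer = c("protein", "transcript")) {
  stopifnot(inherits(x, "IntensityMatrix"))
  layer <- match.arg(layer)
  if (x$scale != "log2") stop("fold changes are computed on the log2 scale", call. = FALSE)
  tp_minus <- unique(x$samples$timepoint[x$samples$condition == "Nminus"])
  tp_plus <- unique(x$samples$timepoint[x$samples$condition == "Nplus"])
  shared <- sort(intersect(tp_minus, tp_plus))
  dropped <- setdiff(union(tp_minus, tp_plus), shared)
  if (length(dropped)) {
    warning("timepoint(s) present in one condition only, excluded: ",
            paste(sort(dropped), collapse = ", "), call. = FALSE)
  }
  if (!length(shared)) stop("no shared timepoints between conditions", call. = FALSE)
  fc <- vapply(shared, function(tp) {
    minus <- x$samples$condition == "Nminus" & x$samples$timepoint == tp
    plus <- x$samples$condition == "Nplus" & x$samples$timepoint == tp
    rowMeans(x$values[, minus, drop = FALSE]) -
      rowMeans(x$values[, plus, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (is.null(dim(fc))) fc <- matrix(fc, nrow = 1)
  rownames(fc) <- rownames(x$values)
  fold_change_table(fc, shared, layer)
}

#' Per-timepoint differential test with FDR control
#'
#' For each entity at each timepoint, a two-sample t test of the N- replicate
#' log2 values against the N+ replicates (Welch's unequal-variance form by
#' default), with Benjamini-Hochberg adjustment across entities within each
#' timepoint. Degenerate groups follow a fixed convention: zero variance in
#' both groups with equal means gives p = 1, with unequal means p = 0.
#'
#' @param x a log2-scale, imputed [intensity_matrix()] with >= 2 replicates
#'   per condition per timepoint.
#' @param level FDR level; `significant` is `q <= level`.
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return data.frame with `entity_id`, `timepoint`, `t_statistic`,
#'   `p_value`, `q_value`, `significant`.
#' @export
differential_test <- function(x, level = 0.05, var_equal = FALSE) {
  stopifnot(inherits(x, "IntensityMatrix"))
  if (x$scale != "log2") stop("test on the log2 scale", call. = FALSE)
  tps <- sort(intersect(
    x$samples$timepoint[x$samples$condition == "Nminus"],
    x$samples$timepoint[x$samples$condition == "Nplus"]
  ))
  out <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    tp <- tps[i]
    a <- x$values[, x$samples$condition == "Nminus" & x$samples$timepoint == tp,
                  drop = FALSE]
    b <- x$values[, x$samples$condition == "Nplus" & x$samples$timepoint == tp,
                  drop = FALSE]
    if (ncol(a) < 2 || ncol(b) < 2) {
      stop("need >= 2 replicates per condition at timepoint ", tp, call. = FALSE)
    }
    tt <- welch_rows(a, b, var_equal = var_equal)
    q <- stats::p.adjust(tt$p, method = "BH")
    out[[i]] <- data.frame(
      entity_id = rownames(x$values),
      timepoint = tp,
      t_statistic = tt$t,
      p_value = tt$p,
      q_value = q,
      significant = q <= level,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Row-wise two-sample t test, vectorised; closed-form Welch-Satterthwaite df.
welch_rows <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- se == 0 | !is.finite(se)
  if (any(zero_var)) {
    equal <- zero_var & (ma == mb)
    t[zero_var & equal] <- 0
    p[zero_var & equal] <- 1
    t[zero_var & !equal] <- sign(ma - mb)[zero_var & !equal] * Inf
    p[zero_var & !equal] <- 0
    message(sum(zero_var), " test(s) with zero variance in both groups; ",
            "p set by convention")
  }
  list(t = unname(t), p = unname(p))
}
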