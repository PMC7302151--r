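#' Z-normalize a series
#'
#' Centres a series to mean 0 and scales it to unit population standard
#' deviation (the `1/m` variance convention used throughout the shape-based
#' distance machinery, so that a z-normalized series of length m has squared
#' norm exactly m). A constant series cannot be scaled; it is returned as the
#' all-zero vector carrying a `degenerate` attribute.
#'
#' @param x numeric vector, length >= 2, finite.
#' @return the normalized vector; `attr(, "degenerate")` is `TRUE` for
#'   constant input.
#' @export
znormalize <- function(x) {
  if (length(x) < 2) stop("domain error: need length >= 2", call. = FALSE)
  if (any(!is.finite(x))) stop("domain error: non-finite value in series", call. = FALSE)
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - mu) / s
  attr(out, "degenerate") <- FALSE
  out
}

is_degenerate <- function(x) isTRUE(attr(znormalize(x), "degenerate"))

#' Coefficient-normalized cross-correlation
#'
#' Computes the full cross-correlation sequence between two equal-length
#' series at every integer shift `w` in `[-(m-1), m-1]`, normalized by the
#' product of the two series' Euclidean norms so every coefficient lies in
#' `[-1, 1]`. Inputs are z-normalized internally, which makes the measure
#' invariant to additive offsets and positive rescaling.
#'
#' Sign convention: at shift `w` the second series is advanced by `w`
#' positions, so a positive `w` at the maximum means `y` lags `x` — e.g. a
#' protein trajectory trailing its transcript gives a positive best shift in
#' `ncc_c(transcript, protein)`.
#'
#' The O(m log m) computation runs through [stats::fft()]; an O(m^2) sliding
#' dot product (`ncc_c_direct()`) is kept as the cross-checking oracle.
#'
#' @param x,y numeric vectors of equal length m >= 2.
#' @return numeric vector of length `2m - 1`; element `i` is the coefficient
#'   at shift `i - m` (shifts attached as the `shifts` attribute).
#' @export
ncc_c <- function(x, y) {
  check_pair(x, y)
  m <- length(x)
  xz <- strip_attr(znormalize(x))
  yz <- strip_attr(znormalize(y))
  denom <- sqrt(sum(xz^2) * sum(yz^2))
  n <- 2L * m - 1L
  fx <- stats::fft(c(xz, rep(0, m - 1L)))
  fy <- stats::fft(c(yz, rep(0, m - 1L)))
  # circular cross-correlation r[k] = sum_i x[i] y[i + k]  (zero-padded)
  r <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / n
  cc <- c(r[(m + 1L):n], r[1L:m])  # shifts -(m-1) .. 0 .. (m-1)
  out <- if (denom == 0) rep(0, n) else cc / denom
  out <- pmin(pmax(out, -1), 1)
  attr(out, "shifts") <- seq.int(-(m - 1L), m - 1L)
  out
}

#' @rdname ncc_c
#' @export
ncc_c_direct <- function(x, y) {
  check_pair(x, y)
  m <- length(x)
  xz <- strip_attr(znormalize(x))
  yz <- strip_attr(znormalize(y))
  denom <- sqrt(sum(xz^2) * sum(yz^2))
  shifts <- seq.int(-(m - 1L), m - 1L)
  cc <- vapply(shifts, function(w) {
    i <- seq_len(m)
    ok <- i + w >= 1L & i + w <= m
    sum(xz[i[ok]] * yz[i[ok] + w])
  }, numeric(1))
  out <- if (denom == 0) rep(0, length(cc)) else cc / denom
  attr(out, "shifts") <- shifts
  out
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("domain error: series must have equal length (no resampling is done)",
         call. = FALSE)
  }
  if (length(x) < 2) stop("domain error: need length >= 2", call. = FALSE)
  invisible(TRUE)
}

strip_attr <- function(x) {
  attributes(x) <- NULL
  x
}

#' Shape-based distance between two series
#'
#' `SBD(x, y) = 1 - max_w NCCc(x, y)[w]`, in `[0, 2]`: 0 for series identical
#' in shape up to shift and positive affine rescaling, 1 for uncorrelated
#' shapes, 2 for exactly opposite shapes. Ties at the maximum are broken
#' toward the smallest absolute shift, then the negative one.
#'
#' Degenerate (constant) series carry no shape. By convention two constant
#' series are at distance 0 from each other, and a constant series is at the
#' uninformative midpoint 1 from any non-constant series.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `distance`, `best_shift` (positive when `y` lags `x`)
#'   and `ncc_max`.
#' @export
sbd <- function(x, y) {
  check_pair(x, y)
  dx <- is_degenerate(x); dy <- is_degenerate(y)
  if (dx && dy) return(list(distance = 0, best_shift = 0L, ncc_max = 1))
  if (dx || dy) return(list(distance = 1, best_shift = 0L, ncc_max = 0))
  cc <- ncc_c(x, y)
  shifts <- attr(cc, "shifts")
  top <- max(cc)
  cand <- which(cc >= top - 1e-12)
  # tie-break: smallest |shift|, then negative before positive
  cand <- cand[order(abs(shifts[cand]), shifts[cand])]
  best <- cand[1]
  list(distance = 1 - top, best_shift = as.integer(shifts[best]),
       ncc_max = top)
}

#' Pair transcript and protein fold-change profiles
#'
#' Restricts two fold-change tables to their shared entities and shared
#' timepoints (ascending), the form consumed by the SBD comparison. With the
#' study design, a six-timepoint protein table meets a five-timepoint
#' transcript table on the five shared hours.
#'
#' @param fc_t transcript-layer [fold_change_table()].
#' @param fc_p protein-layer [fold_change_table()].
#' @return list with matrices `transcript` and `protein` (same rownames, one
#'   column per shared timepoint), `timepoints`, and character vectors
#'   `unpaired_transcript` / `unpaired_protein`.
#' @export
pair_profiles <- function(fc_t, fc_p) {
  stopifnot(inherits(fc_t, "FoldChangeTable"), inherits(fc_p, "FoldChangeTable"))
  shared_tp <- sort(intersect(fc_t$timepoints, fc_p$timepoints))
  if (length(shared_tp) < 3) {
    stop("configuration error: fewer than 3 shared timepoints", call. = FALSE)
  }
  ids_t <- rownames(fc_t$values); ids_p <- rownames(fc_p$values)
  shared <- intersect(ids_t, ids_p)
  list(
    transcript = fc_t$values[shared, match(shared_tp, fc_t$timepoints), drop = FALSE],
    protein = fc_p$values[shared, match(shared_tp, fc_p$timepoints), drop = FALSE],
    timepoints = shared_tp,
    unpaired_transcript = setdiff(ids_t, shared),
    unpaired_protein = setdiff(ids_p, shared)
  )
}

#' SBD between every paired transcript/protein trajectory
#'
#' @param pairs output of [pair_profiles()].
#' @return data.frame with one row per shared entity: `entity_id`, `sbd`,
#'   `best_shift` (positive = protein lags transcript), `ncc_max`.
#' @export
sbd_records <- function(pairs) {
  ids <- rownames(pairs$transcript)
  res <- lapply(seq_along(ids), function(i) {
    s <- sbd(pairs$transcript[i, ], pairs$protein[i, ])
    data.frame(entity_id = ids[i], sbd = s$distance,
               best_shift = s$best_shift, ncc_max = s$ncc_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify transcript-protein concordance by SBD quartiles
#'
#' Genes whose transcript/protein SBD falls strictly below the lower quartile
#' of the reference SBD distribution are called `highly_similar`; strictly
#' above the upper quartile, `highly_unsimilar`; everything else
#' `indistinct`. Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7). By default the reference set is all paired
#' genes, so per-category fractions can then be read off subsets against the
#' global thresholds.
#'
#' @param records data.frame from [sbd_records()].
#' @param reference numeric vector of SBD values defining the quartiles
#'   (default: `records$sbd`); length >= 4 required.
#' @return list with `records` (input plus `similarity_class`) and
#'   `thresholds` (`q1`, `q3`, `n`).
#' @export
classify_similarity <- function(records, reference = records$sbd) {
  if (length(reference) < 4) {
    stop("reference set must contain at least 4 SBD values", call. = FALSE)
  }
  qs <- stats::quantile(reference, c(0.25, 0.75), names = FALSE, type = 7)
  cls <- rep("indistinct", nrow(records))
  cls[records$sbd < qs[1]] <- "highly_similar"
  cls[records$sbd > qs[2]] <- "highly_unsimilar"
  records$similarity_class <- cls
  list(records = records,
       thresholds = list(q1 = qs[1], q3 = qs[2], n = length(reference)))
}

# Shift a series by w positions with zero padding: out[i] = x[i - w].
# Positive w delays the series (content moves right).
shift_zero_pad <- function(x, w) {
  m <- length(x)
  out <- numeric(m)
  if (w >= 0) {
    if (w < m) out[(w + 1):m] <- x[1:(m - w)]
  } else {
    if (-w < m) out[1:(m + w)] <- x[(1 - w):m]
  }
  out
}

#' Extract the shape centroid of a cluster
#'
#' The k-shape shape-extraction step: every member is aligned to the current
#' centroid at its optimal SBD shift (zero-padded), and the new centroid is
#' the principal eigenvector of `Q' S Q` with `S = sum_i y_i y_i'` over the
#' aligned members and `Q = I - (1/m) 11'` the centering matrix — the series
#' maximizing the summed squared normalized cross-correlation to the
#' members. The eigenvector's sign is fixed so its correlation with the
#' aligned-member mean is non-negative, and the result is z-normalized.
#'
#' @param members numeric matrix, one member series per row.
#' @param centroid current centroid series (used for alignment); an all-zero
#'   or degenerate centroid skips alignment.
#' @return the new centroid (z-normalized numeric vector). An empty member
#'   set returns `centroid` unchanged with attribute `empty = TRUE`.
#' @export
kshape_extract_shape <- function(members, centroid) {
  m <- ncol(members)
  if (nrow(members) == 0) {
    attr(centroid, "empty") <- TRUE
    return(centroid)
  }
  centroid_flat <- all(centroid == 0) || sqrt(mean((centroid - mean(centroid))^2)) == 0
  aligned <- t(vapply(seq_len(nrow(members)), function(i) {
    y <- members[i, ]
    if (centroid_flat || is_degenerate(y)) return(y)
    w <- sbd(centroid, y)$best_shift
    # y lags the centroid by w; advance it by w to align
    shift_zero_pad(y, -w)
  }, numeric(m)))
  S <- crossprod(aligned)                 # sum of y y' over aligned members
  Q <- diag(m) - matrix(1 / m, m, m)
  M <- Q %*% S %*% Q
  eig <- eigen(M, symmetric = TRUE)
  cent <- eig$vectors[, 1]
  ref <- colMeans(aligned)
  if (sum(cent * (ref - mean(ref))) < 0) cent <- -cent
  out <- znormalize(cent)
  if (isTRUE(attr(out, "degenerate"))) out <- rep(0, m)
  strip_attr(out)
}

#' k-shape clustering of time profiles
#'
#' Iterative-refinement clustering under the shape-based distance: starting
#' from a random assignment, alternate (a) shape extraction per cluster
#' ([kshape_extract_shape()]) and (b) reassignment of every profile to its
#' nearest centroid by SBD, until the assignment is stable or `max_iter` is
#' reached. An emptied cluster is reseeded with the profile farthest from its
#' current centroid.
#'
#' @param profiles numeric matrix, one series per row (rownames = ids).
#' @param k number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed integer seed for the initial assignment (private stream; the
#'   global RNG is untouched).
#' @param max_iter iteration cap.
#' @return list of class `KShapeModel`: `k`, `assignments` (named integer
#'   vector), `centroids` (k x m matrix), `n_iterations`, `converged`,
#'   `objective` (per-iteration sum of member SBDs), `seed`.
#' @export
kshape_cluster <- function(profiles, k, seed = 1L, max_iter = 100L) {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles); m <- ncol(profiles)
  if (k < 1 || k > n) stop("domain error: need 1 <= k <= n", call. = FALSE)
  rng <- local_rng(seed)
  assign_now <- c(seq_len(k), rng$sample_int(k, n - k, replace = TRUE))
  assign_now <- assign_now[rng$sample_int(n, n)]  # shuffle, every cluster seeded
  centroids <- matrix(0, k, m)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  dist_to <- matrix(Inf, n, k)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      centroids[j, ] <- kshape_extract_shape(
        profiles[assign_now == j, , drop = FALSE], centroids[j, ])
    }
    for (j in seq_len(k)) {
      dist_to[, j] <- vapply(seq_len(n), function(i) {
        sbd(centroids[j, ], profiles[i, ])$distance
      }, numeric(1))
    }
    assign_new <- max.col(-dist_to, ties.method = "first")
    for (j in seq_len(k)) {                    # reseed emptied clusters
      if (!any(assign_new == j)) {
        worst <- which.max(dist_to[cbind(seq_len(n), assign_new)])
        assign_new[worst] <- j
      }
    }
    objective <- c(objective, sum(dist_to[cbind(seq_len(n), assign_new)]))
    if (all(assign_new == assign_now)) {
      converged <- TRUE
      assign_now <- assign_new
      break
    }
    assign_now <- assign_new
  }
  names(assign_now) <- rownames(profiles)
  structure(
    list(k = k, assignments = assign_now, centroids = centroids,
         n_iterations = iter, converged = converged, objective = objective,
         seed = as.integer(seed)),
    class = "KShapeModel"
  )
}

#' @export
print.KShapeModel <- function(x, ...) {
  cat("KShapeModel: k =", x$k, "|", length(x$assignments), "profiles |",
      x$n_iterations, "iteration(s) |",
      if (x$converged) "converged" else "iteration cap reached", "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}
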