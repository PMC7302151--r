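#' Generate paired transcript/protein fold-change trajectories
#'
#' Builds a synthetic ground-truth fixture for the SBD pathway. Every gene
#' gets a transcript trajectory drawn as a smooth random profile (cumulative
#' sum of Gaussian steps). For a `frac_delayed` fraction of genes the protein
#' trajectory is a delayed copy: the transcript shifted right by `delay`
#' timepoint indices (edge-padded with its first value), rescaled by a
#' positive factor, plus Gaussian noise — the "protein response lags
#' transcription" regime. The remaining genes get an independent fresh
#' trajectory plus noise.
#'
#' @param n_pairs number of genes.
#' @param frac_delayed fraction in \[0, 1\] generated as delayed copies.
#' @param m number of timepoints (>= 3); the default 5 mirrors the shared
#'   3/6/12/24/48 h design, whose hours label the columns for `m <= 6`.
#' @param delay_range integer delays sampled uniformly for delayed pairs.
#' @param noise_sd SD of the additive Gaussian noise on the protein layer
#'   (log2-ratio units).
#' @param scale_range range of the positive amplitude rescaling applied to
#'   delayed copies.
#' @param step_sd SD of the random-walk increments of the base trajectories.
#' @param seed integer seed; identical parameters and seed give identical
#'   fixtures.
#' @return list with `transcript` and `protein` ([fold_change_table()]s over
#'   the same genes) and `truth` (data.frame: `entity_id`, `is_delayed_copy`,
#'   `delay`, `scale`, `noise_sd`, `seed`).
#' @export
generate_paired_series <- function(n_pairs, frac_delayed = 0.5, m = 5,
                                   delay_range = 0:2, noise_sd = 0.2,
                                   scale_range = c(0.5, 2), step_sd = 1,
                                   seed = 1L) {
  stopifnot(frac_delayed >= 0, frac_delayed <= 1, m >= 3)
  if (any(delay_range >= m)) {
    stop("configuration error: delay must be smaller than the series length",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  tp <- default_timepoints(m)
  ids <- sprintf("gene_%04d", seq_len(n_pairs))
  n_delayed <- round(frac_delayed * n_pairs)
  delayed <- seq_len(n_pairs) <= n_delayed
  tmat <- matrix(0, n_pairs, m, dimnames = list(ids, NULL))
  pmat <- matrix(0, n_pairs, m, dimnames = list(ids, NULL))
  delays <- integer(n_pairs)
  scales <- rep(1, n_pairs)
  for (i in seq_len(n_pairs)) {
    base <- cumsum(rng$rnorm(m, 0, step_sd))
    tmat[i, ] <- base
    if (delayed[i]) {
      d <- delay_range[rng$sample_int(length(delay_range), 1)]
      a <- rng$runif(1, scale_range[1], scale_range[2])
      shifted <- c(rep(base[1], d), base)[seq_len(m)]  # edge-padded delay
      pmat[i, ] <- a * shifted + rng$rnorm(m, 0, noise_sd)
      delays[i] <- d
      scales[i] <- a
    } else {
      pmat[i, ] <- cumsum(rng$rnorm(m, 0, step_sd)) + rng$rnorm(m, 0, noise_sd)
    }
  }
  list(
    transcript = fold_change_table(tmat, tp, "transcript"),
    protein = fold_change_table(pmat, tp, "protein"),
    truth = data.frame(
      entity_id = ids, is_delayed_copy = delayed, delay = delays,
      scale = scales, noise_sd = noise_sd, seed = as.integer(seed),
      stringsAsFactors = FALSE)
  )
}

default_timepoints <- function(m) {
  study <- c(3, 6, 12, 24, 48, 240)
  if (m <= length(study)) study[seq_len(m)] else 3 * 2^(seq_len(m) - 1)
}

#' Generate an LFQ intensity matrix with intensity-dependent missingness
#'
#' Simulates a label-free proteome experiment: per-entity baseline log2
#' abundances, condition/timepoint effects, replicate noise, and
#' missing-not-at-random dropout whose probability is logistic in the log2
#' intensity — `p_missing = plogis(missing_intercept - missing_slope *
#' log2_intensity)` — so low-abundance measurements are the ones lost, the
#' regime that motivates down-shifted imputation. `missing_intercept = -Inf`
#' disables missingness entirely.
#'
#' @param n_entities number of proteins.
#' @param timepoints vector of hours (default: the study's six).
#' @param n_reps replicates per condition per timepoint (default 3).
#' @param effect_sd SD of the per-entity-per-timepoint N- effect added on
#'   the log2 scale (0 gives a null experiment).
#' @param baseline_mean,baseline_sd distribution of per-entity baseline log2
#'   abundances.
#' @param rep_sd replicate noise SD (log2 scale).
#' @param missing_intercept,missing_slope logistic dropout parameters;
#'   `missing_slope >= 0` enforces the MNAR direction.
#' @param seed integer seed.
#' @return list with `matrix` (a raw-scale [intensity_matrix()]; dropout
#'   cells are missing) and `truth` (per-cell true log2 means, the dropout
#'   parameters and the seed).
#' @export
generate_lfq_matrix <- function(n_entities, timepoints = c(3, 6, 12, 24, 48, 240),
                                n_reps = 3, effect_sd = 1,
                                baseline_mean = 25, baseline_sd = 2,
                                rep_sd = 0.3,
                                missing_intercept = -Inf, missing_slope = 0.5,
                                seed = 1L) {
  stopifnot(missing_slope >= 0, n_reps >= 2)
  rng <- local_rng(seed)
  design <- expand.grid(replicate = seq_len(n_reps), timepoint = timepoints,
                        condition = c("Nminus", "Nplus"),
                        stringsAsFactors = FALSE)[, c("condition", "timepoint", "replicate")]
  ids <- sprintf("prot_%04d", seq_len(n_entities))
  baseline <- rng$rnorm(n_entities, baseline_mean, baseline_sd)
  effects <- matrix(rng$rnorm(n_entities * length(timepoints), 0, effect_sd),
                    n_entities, length(timepoints))
  mu <- matrix(0, n_entities, nrow(design))
  for (s in seq_len(nrow(design))) {
    tp_i <- match(design$timepoint[s], timepoints)
    mu[, s] <- baseline +
      if (design$condition[s] == "Nminus") effects[, tp_i] else 0
  }
  log2_int <- mu + matrix(rng$rnorm(length(mu), 0, rep_sd),
                          n_entities, nrow(design))
  p_miss <- stats::plogis(missing_intercept - missing_slope * log2_int)
  drop <- matrix(rng$runif(length(mu)) < p_miss, n_entities, nrow(design))
  if (any(colSums(!drop) == 0)) {
    stop("dropout parameters produced an all-missing sample column", call. = FALSE)
  }
  values <- 2^log2_int
  values[drop] <- NA_real_
  rownames(values) <- ids
  colnames(values) <- sample_labels(design)
  list(
    matrix = intensity_matrix(values, design, scale = "raw"),
    truth = list(log2_means = mu, baseline = baseline, effects = effects,
                 missing_intercept = missing_intercept,
                 missing_slope = missing_slope, seed = as.integer(seed))
  )
}
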