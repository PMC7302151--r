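# Shared fixture builders and independent oracles.

# Minimal two-condition design: n_tp timepoints x n_rep replicates per side.
make_design <- function(n_tp = 2, n_rep = 3, timepoints = c(3, 6, 12, 24, 48, 240)[seq_len(n_tp)]) {
  expand.grid(replicate = seq_len(n_rep), timepoint = timepoints,
              condition = c("Nminus", "Nplus"),
              stringsAsFactors = FALSE)[, c("condition", "timepoint", "replicate")]
}

make_matrix <- function(values, design, scale = "raw", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("e%02d", seq_len(nrow(values)))
  rownames(values) <- ids
  intensity_matrix(values, design, scale = scale)
}

# Brute-force Benjamini-Hochberg q-values straight from the step-up
# definition: sort p ascending, q_(i) = min_{j >= i} p_(j) * n / j, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- ps * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(q, 1)
  out
}

# Rank-based AUC: probability that a delayed pair scores below an independent
# one (ties split).
rank_auc <- function(scores_pos_low, scores_neg) {
  mean(outer(scores_pos_low, scores_neg, "<")) +
    0.5 * mean(outer(scores_pos_low, scores_neg, "=="))
}

# Interior Gaussian-bump series: unimodal, autocorrelation decaying with lag,
# and placed so that a delay of up to d_max keeps the bump inside the window.
# The regime where integer shifts are identifiable from 5-10 point series.
bump_series <- function(m, d_max, center = NULL, width = NULL) {
  if (is.null(center)) center <- stats::runif(1, 2.5, m - d_max - 1)
  if (is.null(width)) width <- stats::runif(1, 0.5, 1.0)
  exp(-((seq_len(m)) - center)^2 / (2 * width^2))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
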