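#' Read a pipeline configuration file
#'
#' YAML configuration mirroring the arguments of [run_pipeline()]: input
#' paths (`proteome`, `transcriptome`, `annotations`), an output directory,
#' the proteome/transcriptome sample maps (lists with `column`, `condition`,
#' `timepoint`, `replicate` vectors), and parameter blocks `preprocess`
#' (`min_fraction`, `mode`, `width`, `down_shift`, `fdr_level`, `seed`),
#' `clustering` (`k_rows`, `n_phases`, `linkage`) and `sbd` (`seed`).
#'
#' @param path YAML file path.
#' @return a config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("proteome_map", "transcriptome_map")) {
    if (!is.null(cfg[[key]])) {
      cfg[[key]] <- sample_map(cfg[[key]]$column, cfg[[key]]$condition,
                               cfg[[key]]$timepoint, cfg[[key]]$replicate)
    }
  }
  cfg
}

cfg_get <- function(cfg, path, default) {
  node <- cfg
  for (key in path) {
    if (is.null(node[[key]])) return(default)
    node <- node[[key]]
  }
  node
}

#' Run the full integration pipeline
#'
#' End-to-end orchestration of the analysis stages in study order: read the
#' proteome and transcriptome tables; log2 transform; half-of-samples filter
#' and down-shifted imputation on the protein layer; replicate-mean fold
#' changes on both layers; per-timepoint differential tests; hierarchical
#' row clustering, column phase grouping and sample PCA; SBD
#' pairing/classification of transcript vs protein trajectories; and
#' per-cluster category summaries plus the per-category delta matrix when
#' annotations are supplied. Every intermediate table is written as TSV
#' under `cfg$output_dir`, and a manifest recording parameters, seeds and
#' row counts at each stage is returned (and written as YAML).
#'
#' @param cfg configuration list, typically from [read_pipeline_config()].
#'   Inputs can alternatively be passed pre-loaded via `cfg$proteome_matrix`
#'   / `cfg$transcriptome_matrix` ([intensity_matrix()] objects) and
#'   `cfg$annotation_table`, which is how the synthetic fixtures are run.
#' @return the manifest, invisibly a list; see `manifest$counts` for the
#'   per-stage row counts.
#' @export
run_pipeline <- function(cfg) {
  out_dir <- cfg_get(cfg, "output_dir", default = stop("output_dir required", call. = FALSE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("proteoshape")),
    parameters = list(
      min_fraction = cfg_get(cfg, c("preprocess", "min_fraction"), 0.5),
      filter_mode = cfg_get(cfg, c("preprocess", "mode"), "sample"),
      width = cfg_get(cfg, c("preprocess", "width"), 0.3),
      down_shift = cfg_get(cfg, c("preprocess", "down_shift"), 1.8),
      fdr_level = cfg_get(cfg, c("preprocess", "fdr_level"), 0.05),
      impute_seed = cfg_get(cfg, c("preprocess", "seed"), 1L),
      k_rows = cfg_get(cfg, c("clustering", "k_rows"), 8L),
      n_phases = cfg_get(cfg, c("clustering", "n_phases"), 3L),
      linkage = cfg_get(cfg, c("clustering", "linkage"), "average")
    ),
    counts = list(), notes = character(0)
  )

  # --- load -----------------------------------------------------------
  prot_raw <- if (!is.null(cfg$proteome_matrix)) cfg$proteome_matrix else
    read_protein_groups(cfg$proteome, cfg$proteome_map,
                        id_col = cfg_get(cfg, "proteome_id_col", "Protein IDs"))
  manifest$counts$proteome_identified <- nrow(prot_raw$values)
  message("proteome: ", nrow(prot_raw$values), " entities loaded")

  trans_raw <- if (!is.null(cfg$transcriptome_matrix)) cfg$transcriptome_matrix else
    read_fpkm_matrix(cfg$transcriptome, cfg$transcriptome_map,
                     geo_dialect = cfg_get(cfg, "geo_dialect", FALSE))
  manifest$counts$transcriptome_genes <- nrow(trans_raw$values)

  ann <- if (!is.null(cfg$annotation_table)) cfg$annotation_table else
    if (!is.null(cfg$annotations))
      read_annotations(cfg$annotations,
                       cfg_get(cfg, "category_vocabulary",
                               default_category_vocabulary())) else NULL

  # --- protein preprocessing -----------------------------------------
  prot_log <- log2_transform(prot_raw)
  filt <- filter_min_quantified(prot_log,
                                min_fraction = manifest$parameters$min_fraction,
                                mode = manifest$parameters$filter_mode)
  manifest$counts$proteome_after_filter <- length(filt$report$kept_ids)
  message("filter: ", length(filt$report$kept_ids), " proteins remained (",
          manifest$parameters$filter_mode, "-level, min_fraction ",
          manifest$parameters$min_fraction, ")")
  prot_imp <- impute_downshifted_normal(filt$matrix,
                                        width = manifest$parameters$width,
                                        down_shift = manifest$parameters$down_shift,
                                        seed = manifest$parameters$impute_seed)
  write_intensity_matrix(prot_imp, file.path(out_dir, "proteome_log2_imputed.tsv"))

  fc_p <- fold_change(prot_imp, "protein")
  write_results_table(fc_p$values, file.path(out_dir, "fold_change_protein.tsv"))

  diff <- differential_test(prot_imp, level = manifest$parameters$fdr_level)
  manifest$counts$significant_tests <- sum(diff$significant)
  write_results_table(diff, file.path(out_dir, "differential_tests.tsv"))

  # --- transcript layer ----------------------------------------------
  trans_log <- log2_transform(trans_raw)
  fc_t <- fold_change(trans_log, "transcript")
  write_results_table(fc_t$values, file.path(out_dir, "fold_change_transcript.tsv"))

  # --- structure discovery -------------------------------------------
  d <- spearman_distance_matrix(fc_p)
  assignments <- hierarchical_cut(d, k = manifest$parameters$k_rows,
                                  linkage = manifest$parameters$linkage)
  manifest$counts$row_clusters <- length(unique(assignments))
  write_results_table(
    data.frame(entity_id = names(assignments), cluster = unname(assignments)),
    file.path(out_dir, "row_clusters.tsv"))
  write_results_table(cluster_means(fc_p, assignments),
                      file.path(out_dir, "cluster_means.tsv"))
  phases <- column_phase_grouping(fc_p, n_phases = manifest$parameters$n_phases,
                                  linkage = manifest$parameters$linkage)
  write_results_table(phases, file.path(out_dir, "column_phases.tsv"))
  pca <- pca_samples(prot_imp)
  write_results_table(
    cbind(pca$samples, as.data.frame(pca$scores[, 1:min(5, ncol(pca$scores))])),
    file.path(out_dir, "pca_sample_scores.tsv"))

  # heatmap-ready long export
  long <- data.frame(
    entity_id = rep(rownames(fc_p$values), times = length(fc_p$timepoints)),
    timepoint = rep(fc_p$timepoints, each = nrow(fc_p$values)),
    value = as.vector(fc_p$values),
    cluster = rep(unname(assignments[rownames(fc_p$values)]),
                  times = length(fc_p$timepoints)))
  write_results_table(long, file.path(out_dir, "heatmap_long_protein.tsv"))

  # --- SBD concordance -----------------------------------------------
  pairs <- pair_profiles(fc_t, fc_p)
  manifest$counts$paired_genes <- nrow(pairs$transcript)
  manifest$counts$sbd_timepoints <- length(pairs$timepoints)
  if (length(pairs$unpaired_transcript) || length(pairs$unpaired_protein)) {
    manifest$notes <- c(manifest$notes, paste0(
      length(pairs$unpaired_transcript), " transcript-only and ",
      length(pairs$unpaired_protein), " protein-only entities left unpaired"))
  }
  if (!setequal(pairs$timepoints, fc_p$timepoints)) {
    manifest$notes <- c(manifest$notes, paste0(
      "SBD restricted to ", length(pairs$timepoints), " shared timepoints (",
      paste(pairs$timepoints, collapse = ", "), " h)"))
  }
  recs <- sbd_records(pairs)
  classified <- classify_similarity(recs)
  manifest$counts$highly_similar <-
    sum(classified$records$similarity_class == "highly_similar")
  manifest$counts$highly_unsimilar <-
    sum(classified$records$similarity_class == "highly_unsimilar")
  sbd_out <- classified$records
  sbd_out$q1 <- classified$thresholds$q1
  sbd_out$q3 <- classified$thresholds$q3
  write_results_table(sbd_out, file.path(out_dir, "sbd_classification.tsv"))

  # --- category summaries --------------------------------------------
  if (!is.null(ann)) {
    ann_ids <- ann$entity_id
    covered <- names(assignments) %in% ann_ids
    if (!all(covered)) {
      extra <- data.frame(entity_id = names(assignments)[!covered],
                          category = "unknown", consensus = NA_character_,
                          stringsAsFactors = FALSE)
      common <- intersect(names(ann), names(extra))
      ann <- rbind(ann[common], extra[common])
    }
    write_results_table(top_categories(assignments, ann,
                                       n_top = cfg_get(cfg, c("enrichment", "n_top"), 5)),
                        file.path(out_dir, "top_categories.tsv"))
    write_results_table(category_delta(fc_t, fc_p, ann),
                        file.path(out_dir, "category_delta.tsv"))
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
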