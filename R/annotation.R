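#' Majority-consensus subcellular localization
#'
#' Combines pre-computed per-tool compartment predictions (e.g. SignalP,
#' ChloroP, TargetP) into a single call: the compartment named by a strict
#' plurality of tools wins; a tie at the top count gives `"ambiguous"`; a
#' single call stands as-is. Missing calls (`NA`/empty) are ignored.
#'
#' @param calls character vector of compartment names, one element per tool.
#' @return a compartment name or `"ambiguous"`.
#' @export
majority_consensus <- function(calls) {
  calls <- calls[!is.na(calls) & nzchar(calls)]
  if (!length(calls)) stop("need at least one localization call", call. = FALSE)
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("ambiguous")
  names(tab)[1]
}

#' Fill the consensus column of an annotation table
#'
#' Applies [majority_consensus()] across the given tool columns for every
#' entity; entities with no calls keep `NA`. An optional `override` column
#' (manual/legacy localizations) takes precedence where non-missing.
#'
#' @param annotations data.frame from [read_annotations()].
#' @param tool_cols names of the per-tool call columns; defaults to any of
#'   `signalp`, `chlorop`, `targetp` present.
#' @return the annotation data.frame with `consensus` filled.
#' @export
consensus_localization <- function(annotations,
                                   tool_cols = intersect(c("signalp", "chlorop", "targetp"),
                                                         names(annotations))) {
  if (!length(tool_cols)) {
    warning("no localization tool columns found; consensus left NA", call. = FALSE)
    return(annotations)
  }
  for (i in seq_len(nrow(annotations))) {
    calls <- unlist(annotations[i, tool_cols], use.names = FALSE)
    calls <- calls[!is.na(calls) & nzchar(calls)]
    if (length(calls)) {
      annotations$consensus[i] <- majority_consensus(calls)
    }
  }
  if ("override" %in% names(annotations)) {
    has <- !is.na(annotations$override) & nzchar(annotations$override)
    annotations$consensus[has] <- annotations$override[has]
  }
  annotations
}
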