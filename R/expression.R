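# Spatio-temporal expression divergence between duplicate copies: per-stage
# Jaccard overlap of anatomical expression terms, and the comparison of
# asymmetrically vs non-asymmetrically evolving pairs.

#' Per-stage expression overlap between two duplicate copies
#'
#' For every developmental stage recorded in both profiles, the Jaccard
#' index (intersection over union) of the two anatomy-term sets. Stages in
#' which either gene carries the ubiquitous whole-organism annotation are
#' excluded.
#'
#' @param p1,p2 [expression_profile()] objects for the two copies.
#' @param pair_id Identifier to attach to the result rows.
#' @param ubiquitous_term Sentinel anatomy term marking ubiquitous
#'   expression (default `"whole organism"`).
#' @return Data frame with columns `pair_id`, `stage`, `jaccard`; zero rows
#'   (with a warning) when no shared, non-excluded stage exists.
#' @export
stage_overlap <- function(p1, p2, pair_id = paste(p1$gene_id, p2$gene_id,
                                                  sep = "_"),
                          ubiquitous_term = "whole organism") {
  shared <- intersect(names(p1$stages), names(p2$stages))
  rows <- list()
  for (s in shared) {
    t1 <- p1$stages[[s]]; t2 <- p2$stages[[s]]
    if (ubiquitous_term %in% t1 || ubiquitous_term %in% t2) next
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = pair_id, stage = s,
      jaccard = length(intersect(t1, t2)) / length(union(t1, t2)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning(sprintf("no shared non-ubiquitous stages for pair %s", pair_id))
    return(data.frame(pair_id = character(0), stage = character(0),
                      jaccard = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare expression overlap between asymmetric and non-asymmetric pairs
#'
#' One-sided Wilcoxon rank-sum test of whether the stage-level Jaccard
#' overlaps of asymmetrically evolving duplicate pairs are lower than those
#' of non-asymmetric pairs. By default the per-stage values enter the test
#' unaggregated; set `aggregate = "pair"` to compare per-pair mean overlaps
#' instead.
#'
#' @param asym_overlaps,nonasym_overlaps Data frames from [stage_overlap()]
#'   (rows may pool several pairs).
#' @param aggregate `"stage"` (default) or `"pair"`.
#' @return List with `statistic` and `p_value`.
#' @export
divergence_compare <- function(asym_overlaps, nonasym_overlaps,
                               aggregate = c("stage", "pair")) {
  aggregate <- match.arg(aggregate)
  pick <- function(df) {
    if (nrow(df) == 0L) stop_typed("expression_error", "empty overlap group")
    if (aggregate == "stage") df$jaccard
    else as.numeric(tapply(df$jaccard, df$pair_id, mean))
  }
  a <- pick(asym_overlaps); b <- pick(nonasym_overlaps)
  .ranksum_less(a, b)
}
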