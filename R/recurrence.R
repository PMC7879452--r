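#' Aggregate per-pair DE calls into occurrence counts
#'
#' Occurrence is the recurrence statistic of the pipeline: the number of
#' matched pairs in which a lncRNA is called differentially expressed.
#'
#' @param de_results Output of [run_paired_de()] (q and is_de filled).
#' @param lnc_ids Ids of classified lncRNAs to summarize; lncRNAs tested in
#'   zero pairs get `n_pairs_tested = 0` and `occurrence = 0`.
#' @return Data.frame (`OccurrenceSummary` counts part) with columns
#'   `transcript_id`, `n_pairs_tested`, `occurrence`, `n_up`, `n_down`,
#'   `median_log2fc` (median over DE pairs; `NA` when occurrence is 0);
#'   `consistency`, `rank_score`, `rank` left for the later steps.
#' @export
compute_occurrence <- function(de_results, lnc_ids) {
  stopifnot(all(!is.na(de_results$is_de)))
  if (length(unique(de_results$pair_id)) < 2)
    stop("occurrence needs DE results from at least 2 pairs")
  lnc_ids <- unique(lnc_ids)
  sub <- de_results[de_results$transcript_id %in% lnc_ids, , drop = FALSE]

  out <- data.frame(transcript_id = lnc_ids, n_pairs_tested = 0L,
                    occurrence = 0L, n_up = 0L, n_down = 0L,
                    median_log2fc = NA_real_,
                    consistency = NA_character_, rank_score = NA_real_,
                    rank = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(sub) > 0) {
    tested <- table(sub$transcript_id)
    out$n_pairs_tested <- as.integer(tested[out$transcript_id])
    out$n_pairs_tested[is.na(out$n_pairs_tested)] <- 0L
    de <- sub[sub$is_de, , drop = FALSE]
    if (nrow(de) > 0) {
      for (i in seq_len(nrow(out))) {
        di <- de[de$transcript_id == out$transcript_id[i], , drop = FALSE]
        if (nrow(di) == 0) next
        out$occurrence[i] <- nrow(di)
        out$n_up[i] <- sum(di$direction > 0)
        out$n_down[i] <- sum(di$direction < 0)
        out$median_log2fc[i] <- stats::median(di$log2fc)
      }
    }
  }
  out
}

#' Classify direction consistency of recurrent lncRNAs
#'
#' A lncRNA is recurrent when its occurrence clears `min_occurrence`
#' (strictly by default, matching the "occurrence > 10" rule; set
#' `occurrence_cmp = "ge"` for the inclusive reading). A recurrent lncRNA
#' is `consistent_up` when all but at most `max_discordant` of its DE pairs
#' are up (symmetrically `consistent_down`); otherwise `inconsistent`.
#' Non-recurrent lncRNAs are `not_recurrent`.
#'
#' @param summaries From [compute_occurrence()].
#' @param min_occurrence Occurrence threshold (default 10).
#' @param occurrence_cmp `"gt"` (strict, default) or `"ge"`.
#' @param max_discordant Discordant DE pairs tolerated within a consistent
#'   class (default 0: every DE pair must share one direction).
#' @return `summaries` with `consistency` filled.
#' @export
classify_consistency <- function(summaries, min_occurrence = 10,
                                 occurrence_cmp = c("gt", "ge"),
                                 max_discordant = 0) {
  occurrence_cmp <- match.arg(occurrence_cmp)
  recurrent <- if (occurrence_cmp == "gt")
    summaries$occurrence > min_occurrence
  else summaries$occurrence >= min_occurrence

  cls <- rep("not_recurrent", nrow(summaries))
  up <- recurrent & summaries$n_down <= max_discordant &
    summaries$n_up > summaries$n_down
  down <- recurrent & summaries$n_up <= max_discordant &
    summaries$n_down > summaries$n_up
  cls[recurrent] <- "inconsistent"
  cls[up] <- "consistent_up"
  cls[down] <- "consistent_down"
  summaries$consistency <- cls
  summaries
}

#' Rank consistent candidates by fold change and occurrence
#'
#' Only `consistent_up` / `consistent_down` lncRNAs are rankable. The rank
#' score is the mean of the (average-tie) ranks of occurrence and of
#' |median log2FC|, higher = better; rank 1 is the top candidate. Full ties
#' are broken lexicographically by transcript id so the ordering is
#' independent of input order.
#'
#' @param summaries From [classify_consistency()].
#' @param direction `"both"` (default), `"up"` or `"down"`: which
#'   consistent class to rank.
#' @return The rankable subset with `rank_score` and `rank` filled, ordered
#'   by rank. Zero rankable candidates gives an empty data.frame with a
#'   warning.
#' @export
rank_candidates <- function(summaries, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 both = summaries$consistency %in% c("consistent_up",
                                                     "consistent_down"),
                 up = summaries$consistency == "consistent_up",
                 down = summaries$consistency == "consistent_down")
  ranked <- summaries[keep, , drop = FALSE]
  if (nrow(ranked) == 0) {
    warning("no rankable (consistent) candidates")
    return(ranked)
  }
  ranked$rank_score <- (rank(ranked$occurrence, ties.method = "average") +
                        rank(abs(ranked$median_log2fc),
                             ties.method = "average")) / 2
  ord <- order(-ranked$rank_score, ranked$transcript_id)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  ranked
}
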