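#' Classify transcripts into known and novel candidate lncRNAs
#'
#' Applies the catalog/length/coding-potential rules to every transcript:
#' a transcript is "expressed" iff its raw count reaches `min_count` in at
#' least one sample; expressed transcripts found in the known catalog become
#' `lncRNA_known`; expressed transcripts not in the catalog become
#' `lncRNA_novel_candidate` when they are longer than `min_length` nt and
#' at least `consensus_k` of the three coding-potential callers say
#' non-coding (the default, 3, is unanimity: a single coding call rejects).
#' `protein_coding` records pass through unchanged. Everything else is kept
#' with class `unclassified` and a machine-readable rejection reason:
#' `not_expressed`, `too_short`, `coding_call`, or `missing_calls` for
#' transcripts with no coding-potential row.
#'
#' @param annotation Transcript records ([read_gtf()]).
#' @param catalog Character vector of known-lncRNA ids (may be empty).
#' @param calls Coding-potential calls ([read_coding_calls()]); `TRUE`
#'   means "predicted coding".
#' @param cohort `PairedCohort` supplying the raw counts for the
#'   expression gate. Transcripts absent from the count matrix are treated
#'   as unobserved (not expressed).
#' @param min_count Expression gate: raw count needed in >= 1 sample.
#' @param min_length Length bound in nt, strict (`length_nt > min_length`).
#' @param consensus_k Number of non-coding caller votes required.
#' @return The annotation with `biotype` updated and a `reject_reason`
#'   column (`NA` for classified transcripts). Every input transcript
#'   appears exactly once.
#' @export
classify_transcripts <- function(annotation, catalog, calls, cohort,
                                 min_count = 1, min_length = 200,
                                 consensus_k = 3) {
  validate_annotation(annotation)
  stopifnot(consensus_k >= 1, consensus_k <= 3)
  if (anyDuplicated(calls$transcript_id))
    stop("coding calls validation error: duplicate call rows")
  orphan <- setdiff(calls$transcript_id, annotation$transcript_id)
  if (length(orphan) > 0)
    warning("ignoring coding calls for ", length(orphan),
            " transcripts absent from annotation")

  counts <- cohort$counts
  expressed_ids <- rownames(counts)[
    rowSums(counts >= min_count) >= 1]
  expressed <- annotation$transcript_id %in% expressed_ids

  in_catalog <- annotation$transcript_id %in% catalog
  hit <- match(annotation$transcript_id, calls$transcript_id)
  n_noncoding <- rowSums(!as.matrix(
    calls[, c("caller_1", "caller_2", "caller_3")]))
  votes <- n_noncoding[hit]                    # NA when no call row
  has_calls <- !is.na(hit)
  long_enough <- annotation$length_nt > min_length

  out <- annotation
  out$reject_reason <- NA_character_
  coding <- annotation$biotype == "protein_coding"

  for (i in which(!coding)) {
    if (!expressed[i]) {
      out$biotype[i] <- "unclassified"; out$reject_reason[i] <- "not_expressed"
    } else if (in_catalog[i]) {
      out$biotype[i] <- "lncRNA_known"
    } else if (!long_enough[i]) {
      out$biotype[i] <- "unclassified"; out$reject_reason[i] <- "too_short"
    } else if (!has_calls[i]) {
      out$biotype[i] <- "unclassified"; out$reject_reason[i] <- "missing_calls"
    } else if (votes[i] >= consensus_k) {
      out$biotype[i] <- "lncRNA_novel_candidate"
    } else {
      out$biotype[i] <- "unclassified"; out$reject_reason[i] <- "coding_call"
    }
  }
  out
}

#' Summarize catalog composition
#'
#' Counts known and novel candidate lncRNAs and the percentage known,
#' rounded to two decimals.
#'
#' @param classified Output of [classify_transcripts()].
#' @return A one-row data.frame of class `CatalogSummary` with columns
#'   `n_total`, `n_known`, `n_novel`, `pct_known`.
#' @export
summarize_catalog <- function(classified) {
  catalog_summary(sum(classified$biotype == "lncRNA_known"),
                  sum(classified$biotype == "lncRNA_novel_candidate"))
}

#' Catalog summary from explicit counts
#'
#' @param n_known Number of known lncRNAs.
#' @param n_novel Number of novel candidate lncRNAs.
#' @return A one-row data.frame with `n_total = n_known + n_novel` and
#'   `pct_known = round(100 n_known / n_total, 2)` (`NA` when the total
#'   is zero).
#' @export
catalog_summary <- function(n_known, n_novel) {
  stopifnot(n_known >= 0, n_novel >= 0)
  n_total <- n_known + n_novel
  pct <- if (n_total == 0) NA_real_ else round(100 * n_known / n_total, 2)
  structure(data.frame(n_total = n_total, n_known = n_known,
                       n_novel = n_novel, pct_known = pct),
            class = c("CatalogSummary", "data.frame"))
}
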