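# Gap between two 1-based inclusive spans on one chromosome: 0 when they
# overlap or touch, else the difference between the nearer boundaries
# (lnc end 12,000 vs gene start 60,000 -> 48,000).
.span_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1, start2) - pmin(end1, end2))
}

#' Predict cis targets by the genomic-window rule
#'
#' A protein-coding gene is a cis candidate of a lncRNA when its span
#' intersects the window `[lnc_start - window_bp, lnc_end + window_bp]` on
#' the same chromosome, strand-agnostically ("upstream and downstream" read
#' as a symmetric window) and inclusively at the boundary: a gene at
#' distance exactly `window_bp` is kept. Candidate pairs are found with an
#' interval overlap query; the reported distance is the boundary gap
#' (0 when the spans overlap).
#'
#' @param lnc_records Transcript records of the lncRNAs of interest.
#' @param coding_records Transcript records with biotype `protein_coding`.
#' @param window_bp Window half-width (default 100000).
#' @return Data.frame of `TargetPair` rows: `lnc_id`, `gene_id`,
#'   `mode = "cis"`, `distance_bp`, `r = NA`, `r_pvalue = NA`,
#'   `passes = TRUE`.
#' @export
cis_targets <- function(lnc_records, coding_records, window_bp = 100000) {
  if (window_bp < 0) stop("validation error: window_bp must be >= 0")
  coding_records <- coding_records[coding_records$biotype == "protein_coding",
                                   , drop = FALSE]
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      mode = character(0), distance_bp = integer(0),
                      r = numeric(0), r_pvalue = numeric(0),
                      passes = logical(0))
  if (nrow(lnc_records) == 0 || nrow(coding_records) == 0) return(empty)

  lgr <- GenomicRanges::GRanges(lnc_records$chrom,
                                IRanges::IRanges(lnc_records$start,
                                                 lnc_records$end))
  cgr <- GenomicRanges::GRanges(coding_records$chrom,
                                IRanges::IRanges(coding_records$start,
                                                 coding_records$end))
  hits <- GenomicRanges::findOverlaps(lgr, cgr, maxgap = window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- .span_gap(lnc_records$start[qi], lnc_records$end[qi],
                   coding_records$start[si], coding_records$end[si])
  keep <- gap <= window_bp           # inclusive boundary on our gap metric
  out <- data.frame(lnc_id = lnc_records$transcript_id[qi][keep],
                    gene_id = coding_records$transcript_id[si][keep],
                    mode = "cis", distance_bp = as.integer(gap[keep]),
                    r = NA_real_, r_pvalue = NA_real_, passes = TRUE,
                    stringsAsFactors = FALSE)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

# Pearson r and its two-sided t-transform p-value for two finite vectors.
.pearson <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("correlation needs >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  r <- stats::cor(x, y, method = "pearson")
  r_clamped <- max(-1, min(1, r))
  if (abs(r_clamped) == 1) {
    p <- 0
  } else {
    tstat <- r_clamped * sqrt((n - 2) / (1 - r_clamped^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Predict trans targets by co-expression
#'
#' Pearson correlation between each lncRNA and each protein-coding gene on
#' the normalized log2(CPM+1) scale, computed across all samples (paired
#' and unpaired). A pair is emitted iff `|r| > r_min`, strictly; the
#' t-transform p-value is reported but never filtered on.
#'
#' @param expr A [normalize_cpm()] result with >= 3 samples.
#' @param lnc_ids,coding_ids Row ids to correlate.
#' @param r_min Strict |r| threshold (default 0.95).
#' @param sample_ids Optional subset of samples (e.g. tumor-only).
#' @return Data.frame of `TargetPair` rows with `mode = "trans"`. Pairs
#'   involving a zero-variance vector are skipped with a warning.
#' @export
trans_targets <- function(expr, lnc_ids, coding_ids, r_min = 0.95,
                          sample_ids = NULL) {
  v <- expr$values
  if (!is.null(sample_ids)) v <- v[, sample_ids, drop = FALSE]
  if (ncol(v) < 3) stop("trans correlation needs >= 3 samples")
  lnc_ids <- intersect(lnc_ids, rownames(v))
  coding_ids <- intersect(coding_ids, rownames(v))
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      mode = character(0), distance_bp = integer(0),
                      r = numeric(0), r_pvalue = numeric(0),
                      passes = logical(0))
  if (length(lnc_ids) == 0 || length(coding_ids) == 0) return(empty)

  lv <- t(v[lnc_ids, , drop = FALSE])
  cv <- t(v[coding_ids, , drop = FALSE])
  zero_l <- apply(lv, 2, stats::sd) == 0
  zero_c <- apply(cv, 2, stats::sd) == 0
  if (any(zero_l) || any(zero_c))
    warning("skipping ", sum(zero_l) + sum(zero_c),
            " zero-variance transcripts in trans correlation")
  lv <- lv[, !zero_l, drop = FALSE]
  cv <- cv[, !zero_c, drop = FALSE]
  if (ncol(lv) == 0 || ncol(cv) == 0) return(empty)

  rmat <- stats::cor(lv, cv, method = "pearson")
  hit <- which(abs(rmat) > r_min, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  n <- nrow(lv)
  r <- rmat[hit]
  rc <- pmax(-1, pmin(1, r))
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  pv <- ifelse(abs(rc) == 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  out <- data.frame(lnc_id = colnames(lv)[hit[, 1]],
                    gene_id = colnames(cv)[hit[, 2]],
                    mode = "trans", distance_bp = NA_integer_,
                    r = r, r_pvalue = pv, passes = TRUE,
                    stringsAsFactors = FALSE)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

#' Correlation of one named transcript pair
#'
#' Same estimator as [trans_targets()], exposed for reporting single pairs
#' (e.g. a headline lncRNA-gene link).
#'
#' @param expr A [normalize_cpm()] result.
#' @param id_a,id_b Row ids.
#' @param sample_ids Optional sample subset.
#' @return List with `r` and `r_pvalue`.
#' @export
correlate_pair <- function(expr, id_a, id_b, sample_ids = NULL) {
  v <- expr$values
  if (!is.null(sample_ids)) v <- v[, sample_ids, drop = FALSE]
  if (!all(c(id_a, id_b) %in% rownames(v)))
    stop("transcript id not found in expression matrix")
  res <- .pearson(as.numeric(v[id_a, ]), as.numeric(v[id_b, ]))
  list(r = res$r, r_pvalue = res$p)
}

#' Format a p-value for human-readable reports
#'
#' Values below double precision's smallest meaningful tail are printed as
#' `< 2.2e-16`, the conventional floor; raw floats stay untouched in TSVs.
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3)
}

#' Hypergeometric over-representation of selected genes in gene sets
#'
#' For each set, `p = P(X >= n_hits)` with `X` hypergeometric on population
#' `universe_size`, `set_size` successes and `n_selected` draws (so a set
#' with zero hits gets p = 1). Sets are intersected with the universe
#' before testing; q is Benjamini-Hochberg over all tested sets.
#'
#' @param selected_genes Id set of selected genes (must lie in `universe`).
#' @param gene_sets Named list of id vectors (e.g. from [read_gmt()]).
#' @param universe Id set defining the population.
#' @return Data.frame of `EnrichmentResult` rows: `set_id`, `set_size`,
#'   `n_hits`, `universe_size`, `n_selected`, `p`, `q`.
#' @export
overrepresentation_test <- function(selected_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("enrichment error: empty universe")
  selected_genes <- unique(selected_genes)
  if (!all(selected_genes %in% universe))
    stop("enrichment error: selected genes outside the universe")
  N <- length(universe)
  k <- length(selected_genes)
  res <- lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), universe)
    m <- length(set)
    hits <- length(intersect(set, selected_genes))
    p <- stats::phyper(hits - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_id = sid, set_size = m, n_hits = hits,
               universe_size = N, n_selected = k, p = p, q = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
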