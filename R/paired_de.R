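#' Library-size normalization to log2(CPM + pseudocount)
#'
#' `value[t, s] = log2(1e6 * count[t, s] / libsize[s] + pseudocount)` with
#' `libsize[s]` the total raw count of sample `s`. Deterministic and
#' recomputable from the counts.
#'
#' @param cohort A `PairedCohort`.
#' @param pseudocount Added inside the log (default 1, so a zero count maps
#'   to 0).
#' @return A list of class `NormalizedExpression` with `values` (matrix,
#'   same ids as the counts), `pseudocount` and `libsize`.
#' @export
normalize_cpm <- function(cohort, pseudocount = 1) {
  counts <- cohort$counts
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("normalization error: sample with zero total counts: ",
         colnames(counts)[which(libsize == 0)[1]])
  values <- log2(sweep(counts, 2, libsize, "/") * 1e6 + pseudocount)
  structure(list(values = values, pseudocount = pseudocount,
                 libsize = libsize),
            class = "NormalizedExpression")
}

#' Local-pooled-error test for one matched pair
#'
#' Tests every transcript for tumor-vs-normal differential expression
#' within a single matched pair, with no replicates, by pooling variance
#' locally across transcripts of similar abundance. For each transcript,
#' `d = tumor - normal` on the log2(CPM+1) scale and `a = (tumor+normal)/2`;
#' transcripts are ordered by `a` and split into equal-occupancy abundance
#' bins. Within each bin the null scale is the MAD of `d` around the bin
#' median (`1.4826 * median|d - median(d)|`), robust to a minority of truly
#' differential transcripts; the per-bin scales are smoothed by a running
#' median of 3 and floored at `sigma_min`. Then
#' `z = (d - bin median) / sigma_bin` and `p` is the two-sided standard
#' normal tail. Transcripts below the expression gate in both samples of
#' the pair are excluded from the test (and from the later BH denominator).
#'
#' @param cohort A `PairedCohort`.
#' @param pair_id One of [cohort_pairs()].
#' @param expr Optional precomputed [normalize_cpm()] result.
#' @param bins Target number of equal-occupancy abundance bins.
#' @param min_bin Minimum transcripts per bin; the bin count is reduced on
#'   small inputs so no bin falls below it.
#' @param sigma_min Floor on the pooled scale (log2 units).
#' @param mad_constant Consistency constant for the MAD (1.4826 makes it
#'   estimate a normal standard deviation).
#' @param min_count Expression gate on raw counts.
#' @return Data.frame with `transcript_id`, `pair_id`, `log2fc` (= `d`),
#'   `z`, `p`; `q`, `direction`, `is_de` left `NA` for [call_de()].
#' @export
lpe_test <- function(cohort, pair_id, expr = NULL, bins = 100, min_bin = 30,
                     sigma_min = 0.05, mad_constant = 1.4826,
                     min_count = 1) {
  s <- cohort$samples
  sel <- !is.na(s$pair_id) & s$pair_id == pair_id
  if (sum(sel) != 2)
    stop("pair ", pair_id, " not found or incomplete")
  tumor_id <- s$sample_id[sel & s$condition == "tumor"]
  normal_id <- s$sample_id[sel & s$condition == "normal"]
  if (length(tumor_id) != 1 || length(normal_id) != 1)
    stop("pair ", pair_id, " must have exactly one tumor and one normal")
  if (is.null(expr)) expr <- normalize_cpm(cohort)

  gate <- cohort$counts[, tumor_id] >= min_count |
    cohort$counts[, normal_id] >= min_count
  ids <- rownames(cohort$counts)[gate]
  vt <- expr$values[ids, tumor_id]
  vn <- expr$values[ids, normal_id]
  d <- vt - vn
  a <- (vt + vn) / 2
  n <- length(d)
  if (n == 0)
    return(data.frame(transcript_id = character(0), pair_id = character(0),
                      log2fc = numeric(0), z = numeric(0), p = numeric(0),
                      q = numeric(0), direction = integer(0),
                      is_de = logical(0)))

  n_bins <- max(1L, min(as.integer(bins), n %/% as.integer(min_bin)))
  ord <- order(a, ids)            # id tie-break keeps binning deterministic
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)

  center <- vapply(seq_len(n_bins), function(b)
    stats::median(d[bin == b]), numeric(1))
  sigma <- vapply(seq_len(n_bins), function(b) {
    db <- d[bin == b]
    mad_constant * stats::median(abs(db - stats::median(db)))
  }, numeric(1))
  if (n_bins >= 3) sigma <- as.numeric(stats::runmed(sigma, 3))
  sigma <- pmax(sigma, sigma_min)

  z <- (d - center[bin]) / sigma[bin]
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(transcript_id = ids, pair_id = pair_id, log2fc = as.numeric(d),
             z = as.numeric(z), p = as.numeric(p), q = NA_real_,
             direction = NA_integer_, is_de = NA,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differential expression at q-value and fold-change thresholds
#'
#' Benjamini-Hochberg adjusts the p-values (within each pair by default,
#' since each matched pair is an independent screen) and calls a transcript
#' differentially expressed iff `q < q_max` and `|log2fc| > lfc_min`, both
#' strict inequalities: a transcript at exactly q = 0.05 or |log2FC| = 1 is
#' not called.
#'
#' @param results Rows from [lpe_test()] (one or several pairs).
#' @param q_max Strict q-value threshold.
#' @param lfc_min Strict |log2FC| threshold.
#' @param global_bh If `TRUE`, adjust across all pairs jointly instead of
#'   within pair.
#' @return `results` with `q`, `direction` (sign of `log2fc`) and `is_de`
#'   filled.
#' @export
call_de <- function(results, q_max = 0.05, lfc_min = 1.0,
                    global_bh = FALSE) {
  stopifnot(all(!is.na(results$p)))
  if (global_bh) {
    results$q <- stats::p.adjust(results$p, method = "BH")
  } else {
    for (pid in unique(results$pair_id)) {
      sel <- results$pair_id == pid
      results$q[sel] <- stats::p.adjust(results$p[sel], method = "BH")
    }
  }
  results$direction <- ifelse(results$log2fc > 0, 1L,
                              ifelse(results$log2fc < 0, -1L, 0L))
  results$is_de <- results$q < q_max & abs(results$log2fc) > lfc_min
  results
}

#' Run the paired LPE test over every matched pair of a cohort
#'
#' @param cohort A `PairedCohort` with at least one matched pair.
#' @param q_max,lfc_min Calling thresholds (see [call_de()]).
#' @param ... Passed to [lpe_test()].
#' @return One data.frame with a row per (tested transcript, pair).
#' @export
run_paired_de <- function(cohort, q_max = 0.05, lfc_min = 1.0, ...) {
  pairs <- cohort_pairs(cohort)
  if (length(pairs) == 0) stop("cohort has no matched pairs")
  expr <- normalize_cpm(cohort)
  res <- do.call(rbind, lapply(pairs, function(pid)
    lpe_test(cohort, pid, expr = expr, ...)))
  call_de(res, q_max = q_max, lfc_min = lfc_min)
}
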