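# Shared in-code fixtures: everything is built programmatically at test time.

# A minimal hand-written annotation: two lncRNA-sized transcripts, one
# coding gene, one short transcript.
tiny_annotation <- function() {
  data.frame(
    transcript_id = c("T1", "T2", "T3", "T4"),
    gene_id = c("G1", "G2", "G3", "G4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "."),
    start = c(100L, 5000L, 1000L, 9000L),
    end = c(1099L, 5999L, 3999L, 9149L),
    length_nt = c(1000L, 1000L, 3000L, 150L),
    biotype = c("unclassified", "unclassified", "protein_coding",
                "unclassified"),
    stringsAsFactors = FALSE
  )
}

# Matching 4-sample (2-pair) cohort with easily recognizable counts.
tiny_cohort <- function(counts = NULL) {
  samples <- data.frame(
    sample_id = c("S1_T", "S1_N", "S2_T", "S2_N"),
    condition = c("tumor", "normal", "tumor", "normal"),
    pair_id = c("P1", "P1", "P2", "P2"),
    stringsAsFactors = FALSE
  )
  if (is.null(counts)) {
    counts <- matrix(c(10L, 5L, 8L, 6L,
                       0L, 100L, 2L, 90L,
                       50L, 50L, 55L, 45L,
                       1L, 1L, 0L, 2L),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("T1", "T2", "T3", "T4"),
                                     samples$sample_id))
  }
  paired_cohort(counts, samples, tiny_annotation())
}

# Small, fast simulation config for tests that need a full cohort.
test_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_pairs = 6, n_coding_genes = 80, n_lncRNA = 40,
         n_short_decoys = 4, n_chrom = 2),
    list(...))
  do.call(simulation_config, args)
}

# Independent Pearson oracle: plain covariance-formula computation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Independent hypergeometric upper-tail oracle by direct combinatorial
# summation (choose() on log scale not needed for populations <= 200).
hyper_upper_oracle <- function(hits, set_size, universe, drawn) {
  kmax <- min(set_size, drawn)
  if (hits > kmax) return(0)
  sum(vapply(hits:kmax, function(k)
    choose(set_size, k) * choose(universe - set_size, drawn - k),
    numeric(1))) / choose(universe, drawn)
}

# Build a de_results table from a compact description: for each transcript,
# a vector of per-pair calls coded +1 (DE up), -1 (DE down), 0 (tested, not
# DE).
fake_de <- function(spec, n_pairs = 19, lfc_up = 2, lfc_down = -2) {
  rows <- lapply(names(spec), function(id) {
    calls <- spec[[id]]
    data.frame(transcript_id = id,
               pair_id = sprintf("P%02d", seq_len(n_pairs)),
               log2fc = ifelse(calls > 0, lfc_up,
                               ifelse(calls < 0, lfc_down, 0.1)),
               z = 0, p = 0.5, q = ifelse(calls != 0, 0.01, 0.9),
               direction = ifelse(calls > 0, 1L, ifelse(calls < 0, -1L, 1L)),
               is_de = calls != 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
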