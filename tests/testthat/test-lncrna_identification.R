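# Brute-force reimplementation of the classification rule table, kept
# deliberately different in structure from the package code.
classify_oracle <- function(rec, in_catalog, expressed, votes_noncoding,
                            min_length = 200, consensus_k = 3) {
  if (rec$biotype == "protein_coding") return(c("protein_coding", NA))
  if (!expressed) return(c("unclassified", "not_expressed"))
  if (in_catalog) return(c("lncRNA_known", NA))
  if (rec$length_nt <= min_length) return(c("unclassified", "too_short"))
  if (is.na(votes_noncoding)) return(c("unclassified", "missing_calls"))
  if (votes_noncoding >= consensus_k) return(c("lncRNA_novel_candidate", NA))
  c("unclassified", "coding_call")
}

make_class_fixture <- function(lengths, call_rows, catalog, counts_first) {
  n <- length(lengths)
  ann <- data.frame(
    transcript_id = sprintf("X%02d", seq_len(n)),
    gene_id = sprintf("GX%02d", seq_len(n)),
    chrom = "chr1", strand = "+",
    start = seq(1, by = 10000, length.out = n),
    end = seq(1, by = 10000, length.out = n) + pmax(lengths, 1L) - 1L,
    length_nt = lengths, biotype = "unclassified",
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("A_T", "A_N"),
                        condition = c("tumor", "normal"),
                        pair_id = c("P1", "P1"), stringsAsFactors = FALSE)
  counts <- cbind(A_T = counts_first, A_N = rep(1L, n))
  rownames(counts) <- ann$transcript_id
  list(ann = ann, cohort = paired_cohort(counts, samples, ann),
       calls = call_rows, catalog = catalog)
}

test_that("classification matches a brute-force rule-table oracle", {
  set.seed(42)
  n <- 60
  lengths <- sample(c(100L, 150L, 201L, 300L, 2000L), n, replace = TRUE)
  expressed <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2))
  counts_first <- ifelse(expressed, sample(1:50, n, replace = TRUE), 0L)
  in_catalog <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.3, .7))
  has_calls <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.9, .1))
  call_mat <- matrix(sample(c(TRUE, FALSE), 3 * n, replace = TRUE), ncol = 3)
  fx <- make_class_fixture(lengths, NULL, NULL, counts_first)
  # expression gate is per-row in BOTH columns; second column is all 1s, so
  # force non-expressed rows to 0 in both
  fx$cohort$counts[!expressed, ] <- 0L
  calls <- data.frame(transcript_id = fx$ann$transcript_id[has_calls],
                      caller_1 = call_mat[has_calls, 1],
                      caller_2 = call_mat[has_calls, 2],
                      caller_3 = call_mat[has_calls, 3],
                      stringsAsFactors = FALSE)
  catalog <- fx$ann$transcript_id[in_catalog]

  for (k in c(3, 2)) {
    got <- classify_transcripts(fx$ann, catalog, calls, fx$cohort,
                                consensus_k = k)
    for (i in seq_len(n)) {
      votes <- if (has_calls[i]) sum(!call_mat[i, ]) else NA
      want <- classify_oracle(fx$ann[i, ], in_catalog[i], expressed[i],
                              votes, consensus_k = k)
      expect_identical(got$biotype[i], want[1],
                       label = paste("biotype row", i, "k", k))
      expect_identical(got$reject_reason[i], as.character(want[2]),
                       label = paste("reason row", i, "k", k))
    }
  }
})

test_that("canonical single-transcript rulings hold", {
  fx <- make_class_fixture(c(150L, 300L, 300L), NULL, NULL, c(5L, 5L, 0L))
  fx$cohort$counts[3, ] <- 0L
  calls <- data.frame(transcript_id = c("X01", "X02", "X03"),
                      caller_1 = c(FALSE, FALSE, FALSE),
                      caller_2 = c(FALSE, FALSE, FALSE),
                      caller_3 = c(FALSE, TRUE, FALSE))
  got <- classify_transcripts(fx$ann, catalog = "X03", calls, fx$cohort)
  # expressed, non-coding, but 150 nt
  expect_equal(got$reject_reason[1], "too_short")
  # 300 nt but one caller votes coding, under unanimity
  expect_equal(got$reject_reason[2], "coding_call")
  # in the catalog but never observed
  expect_equal(got$reject_reason[3], "not_expressed")
})

test_that("every transcript lands in exactly one class and the gate is monotone", {
  s <- simulate_cohort(test_sim_config(seed = 2))
  dir <- withr::local_tempdir()
  export_fixture(s$cohort, s$truth, dir)
  catalog <- read_catalog(file.path(dir, "known_catalog.txt"))
  calls <- read_coding_calls(file.path(dir, "coding_calls.tsv"))

  totals <- vapply(c(1, 5, 50), function(mc) {
    cl <- classify_transcripts(s$annotation, catalog, calls, s$cohort,
                               min_count = mc)
    expect_equal(nrow(cl), nrow(s$annotation))
    classified <- cl$biotype != "unclassified"
    expect_true(all(is.na(cl$reject_reason[classified])))
    expect_true(all(!is.na(cl$reject_reason[cl$biotype == "unclassified"])))
    summarize_catalog(cl)$n_total
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("with perfect callers the classification recovers the truth", {
  s <- simulate_cohort(test_sim_config(seed = 4, caller_error_rate = 0))
  dir <- withr::local_tempdir()
  export_fixture(s$cohort, s$truth, dir)
  catalog <- read_catalog(file.path(dir, "known_catalog.txt"))
  calls <- read_coding_calls(file.path(dir, "coding_calls.tsv"))
  cl <- classify_transcripts(s$annotation, catalog, calls, s$cohort)
  roles <- s$truth$roles
  expressed <- rownames(s$cohort$counts)[rowSums(s$cohort$counts >= 1) >= 1]

  lnc <- roles$transcript_id[roles$role == "lncRNA"]
  lnc_expr <- intersect(lnc, expressed)
  expect_setequal(cl$transcript_id[cl$biotype == "lncRNA_known"],
                  intersect(lnc_expr, catalog))
  expect_setequal(cl$transcript_id[cl$biotype == "lncRNA_novel_candidate"],
                  setdiff(lnc_expr, catalog))
  expect_true(all(cl$biotype[roles$role == "coding"] == "protein_coding"))
  short <- intersect(roles$transcript_id[roles$role == "short_decoy"],
                     expressed)
  expect_true(all(cl$reject_reason[cl$transcript_id %in% short] ==
                    "too_short"))
})

test_that("catalog summary arithmetic and rounding conventions", {
  got <- catalog_summary(48551, 9612)
  expect_equal(got$n_total, 58163)
  expect_equal(got$pct_known, 83.47)
  expect_equal(catalog_summary(0, 10)$pct_known, 0)
  expect_equal(catalog_summary(1, 2)$pct_known, 33.33)
  expect_true(is.na(catalog_summary(0, 0)$pct_known))
})
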