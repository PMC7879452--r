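mk_rec <- function(id, chrom, start, end, biotype = "protein_coding") {
  data.frame(transcript_id = id, gene_id = paste0("G_", id), chrom = chrom,
             strand = "+", start = as.integer(start), end = as.integer(end),
             length_nt = as.integer(end - start + 1), biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("cis window rule: gap arithmetic, boundary inclusion, overlap", {
  lnc <- mk_rec("L1", "chr1", 10000, 12000, biotype = "unclassified")
  genes <- rbind(
    mk_rec("near", "chr1", 60000, 61000),      # gap 48,000
    mk_rec("far", "chr1", 115000, 116000),     # gap 103,000
    mk_rec("edge", "chr1", 112000, 113000),    # gap exactly 100,000
    mk_rec("inside", "chr1", 11000, 11500),    # overlapping
    mk_rec("left", "chr1", 1000, 2000),        # gap 8,000 upstream
    mk_rec("otherchrom", "chr2", 60000, 61000)
  )
  got <- cis_targets(lnc, genes)
  expect_setequal(got$gene_id, c("near", "edge", "inside", "left"))
  dist <- setNames(got$distance_bp, got$gene_id)
  expect_equal(dist[["near"]], 48000L)
  expect_equal(dist[["edge"]], 100000L)
  expect_equal(dist[["inside"]], 0L)
  expect_equal(dist[["left"]], 8000L)
  expect_error(cis_targets(lnc, genes, window_bp = -1), "window_bp")
})

test_that("cis pairs match a brute-force all-pairs scan on random loci", {
  set.seed(17)
  n_lnc <- 200; n_gene <- 800
  lnc <- do.call(rbind, lapply(seq_len(n_lnc), function(i) {
    st <- sample.int(5e6, 1)
    mk_rec(sprintf("L%03d", i), sample(paste0("chr", 1:3), 1), st,
           st + sample.int(5000, 1), biotype = "unclassified")
  }))
  genes <- do.call(rbind, lapply(seq_len(n_gene), function(i) {
    st <- sample.int(5e6, 1)
    mk_rec(sprintf("P%03d", i), sample(paste0("chr", 1:3), 1), st,
           st + sample.int(5000, 1))
  }))
  w <- 100000
  got <- cis_targets(lnc, genes, window_bp = w)

  oracle <- list()
  for (i in seq_len(n_lnc)) for (j in seq_len(n_gene)) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    gap <- max(0, max(lnc$start[i], genes$start[j]) -
                 min(lnc$end[i], genes$end[j]))
    if (gap <= w)
      oracle[[length(oracle) + 1]] <- data.frame(
        lnc_id = lnc$transcript_id[i], gene_id = genes$transcript_id[j],
        distance_bp = as.integer(gap), stringsAsFactors = FALSE)
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$lnc_id, oracle$gene_id), ]
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$lnc_id, oracle$lnc_id)
  expect_equal(got$gene_id, oracle$gene_id)
  expect_equal(got$distance_bp, oracle$distance_bp)
})

test_that("Pearson estimator agrees with the covariance-formula oracle", {
  set.seed(7)
  vals <- matrix(rnorm(20 * 6), nrow = 6,
                 dimnames = list(paste0("t", 1:6), paste0("s", 1:20)))
  expr <- structure(list(values = vals, pseudocount = 1,
                         libsize = rep(1, 20)),
                    class = "NormalizedExpression")
  for (a in rownames(vals)) for (b in rownames(vals)) {
    got <- correlate_pair(expr, a, b)
    expect_equal(got$r, pearson_oracle(vals[a, ], vals[b, ]),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(got$r, correlate_pair(expr, b, a)$r, tolerance = 1e-15)
  }
})

test_that("trans rule is strict at |r| = r_min and skips flat transcripts", {
  x <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(lnc = x,
                perfect = 2 * x,
                anti = -x,
                weak = c(1, 2, 3, 4, 5, 2),
                flat = rep(3, 6))
  colnames(vals) <- paste0("s", 1:6)
  expr <- structure(list(values = vals, pseudocount = 1,
                         libsize = rep(1, 6)),
                    class = "NormalizedExpression")
  expect_warning(
    got <- trans_targets(expr, "lnc", c("perfect", "anti", "weak", "flat")),
    "zero-variance")
  expect_setequal(got$gene_id, c("perfect", "anti"))
  expect_equal(got$r[got$gene_id == "perfect"], 1)
  expect_equal(got$r[got$gene_id == "anti"], -1)
  # a correlation just below the threshold is not emitted
  r_weak <- pearson_oracle(x, vals["weak", ])
  expect_lt(abs(r_weak), 0.95)
  # one exactly at the threshold is not emitted either (strict >)
  got2 <- trans_targets(expr, "lnc", "perfect", r_min = 1)
  expect_equal(nrow(got2), 0)
})

test_that("correlation p-values: identity underflow and null symmetry", {
  vals <- rbind(a = c(-1, 0, 1), b = c(1, -2, 1), c = c(-2, 0, 2))
  colnames(vals) <- paste0("s", 1:3)
  expr <- structure(list(values = vals, pseudocount = 1,
                         libsize = rep(1, 3)),
                    class = "NormalizedExpression")
  ident <- correlate_pair(expr, "a", "c")   # y = 2x, r = 1
  expect_equal(ident$r, 1)
  expect_lt(ident$r_pvalue, 2.2e-16)
  expect_equal(format_pvalue(ident$r_pvalue), "< 2.2e-16")
  null3 <- correlate_pair(expr, "a", "b")   # r = 0 with n = 3
  expect_equal(null3$r, 0)
  expect_equal(null3$r_pvalue, 1)
})

test_that("hypergeometric p matches exact combinatorial summation", {
  # closed-form extreme: all 5 draws in a 5-gene set of a 20-gene universe
  universe <- paste0("g", 1:20)
  sets <- list(hot = universe[1:5], cold = universe[6:10])
  got <- overrepresentation_test(universe[1:5], sets, universe)
  expect_equal(got$p[got$set_id == "hot"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(got$p[got$set_id == "cold"], 1)   # zero hits, P(X >= 0)

  set.seed(99)
  for (rep in 1:25) {
    N <- sample(20:200, 1)
    m <- sample.int(N, 1)
    k <- sample.int(N, 1)
    universe <- paste0("u", seq_len(N))
    set <- sample(universe, m)
    selected <- sample(universe, k)
    got <- overrepresentation_test(selected, list(s = set), universe)
    hits <- length(intersect(set, selected))
    expect_equal(got$n_hits, hits)
    expect_equal(got$p, hyper_upper_oracle(hits, m, N, k),
                 tolerance = 1e-12)
  }
  expect_error(overrepresentation_test("g1", list(s = "g1"), character(0)),
               "empty universe")
  expect_error(overrepresentation_test("zz", list(s = "g1"), "g1"),
               "outside the universe")
})

test_that("a proportionate draw is unremarkable to the upper-tail test", {
  # selected genes hit the set exactly at its expected share
  universe <- paste0("g", 1:100)
  set <- universe[1:20]                     # 20% of the universe
  selected <- c(universe[1:4], universe[21:36])   # 4/20 hits = 20%
  got <- overrepresentation_test(selected, list(s = set), universe)
  expect_gt(got$p, 0.5)
  expect_equal(got$p, hyper_upper_oracle(4, 20, 100, 20), tolerance = 1e-12)
})

test_that("planted cis targets are recovered and decoys excluded", {
  s <- simulate_cohort(test_sim_config(seed = 19))
  cl <- s$annotation
  lnc_rec <- cl[grepl("^LNC", cl$transcript_id), ]
  cod_rec <- cl[cl$biotype == "protein_coding", ]
  got <- cis_targets(lnc_rec, cod_rec)
  tg <- s$truth$targets
  cis_true <- tg[tg$mode == "cis_true", ]
  decoys <- tg[tg$mode == "cis_decoy", ]
  key <- function(df, a = "lnc_id", b = "gene_id") paste(df[[a]], df[[b]])
  expect_true(all(key(cis_true) %in% key(got)))
  expect_false(any(key(decoys) %in% key(got)))
  hit <- match(key(cis_true), key(got))
  expect_equal(got$distance_bp[hit], abs(cis_true$distance_bp))
})

test_that("most planted trans pairs clear the correlation threshold", {
  s <- simulate_cohort(simulation_config(seed = 1))
  expr <- normalize_cpm(s$cohort)
  tg <- s$truth$targets[s$truth$targets$mode == "trans_true", ]
  rs <- vapply(seq_len(nrow(tg)), function(i)
    correlate_pair(expr, tg$lnc_id[i], tg$gene_id[i])$r, numeric(1))
  expect_gte(mean(abs(rs) > 0.95), 0.9)
  expect_gte(mean(abs(rs)), 0.95)
})
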