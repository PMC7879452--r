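#' Simulation configuration for synthetic matched tumor-normal cohorts
#'
#' The defaults emulate the study design the package targets: 19 matched
#' tumor-normal pairs, a transcriptome of protein-coding genes plus lncRNA
#' candidates, a minority of lncRNAs carrying planted tumor fold changes
#' (|log2FC| > 1 so planted effects sit above the calling threshold), cis
#' neighbors placed inside and beyond the 100 kb window, and trans targets
#' coupled to their lncRNA through a shared latent factor so the realized
#' |Pearson r| on log2(CPM+1) exceeds 0.95 in expectation.
#'
#' @param n_pairs Number of matched tumor-normal pairs (>= 2).
#' @param n_unpaired_tumor Extra unpaired tumor samples (correlation only).
#' @param n_coding_genes Number of protein-coding genes.
#' @param n_lncRNA Number of lncRNA candidate transcripts (> 200 nt).
#' @param n_short_decoys Number of short (< 200 nt) decoy transcripts.
#' @param frac_de Fraction of lncRNAs with a planted differential effect.
#' @param frac_consistent Fraction of planted-DE lncRNAs whose direction is
#'   identical in every pair; the rest flip direction in `floor(n_pairs/3)`
#'   randomly chosen pairs.
#' @param log2fc_mean,log2fc_sd Normal distribution of planted |log2FC|
#'   magnitudes, resampled until |log2FC| > 1.
#' @param nb_dispersion Negative-binomial dispersion (Var = mu + phi mu^2).
#' @param libsize_range Per-sample library-size multiplier interval.
#' @param base_log2_mean,base_log2_sd Log2-normal baseline mean expression
#'   (relative abundance shape).
#' @param depth_factor Sequencing-depth multiplier applied to every mean;
#'   the default brings per-transcript coverage at this desk-scale
#'   transcriptome to a realistic bulk RNA-seq scale, so low-abundance
#'   transcripts are not dominated by counting noise artifacts of a tiny
#'   library.
#' @param target_log2cpm_mean,target_log2cpm_sd Baseline abundance of the
#'   planted cis-/trans-true target genes, on the log2 CPM scale (about the
#'   cohort median). Planted targets are parameterized in CPM so their
#'   coupled swings stay a bounded fraction of the library, and at
#'   quantifiable abundance: a 0.95 correlation is not realizable for
#'   counting-noise-dominated transcripts.
#' @param cis_window_bp Cis window half-width in bp.
#' @param n_cis_true,n_trans_true Planted targets per DE lncRNA.
#' @param trans_coupling Latent-factor loading tying a planted target's
#'   log2 mean to its lncRNA's realized log2 expression.
#' @param trans_latent_sd Gaussian noise on the latent coupling; the default
#'   keeps planted |r| >= 0.95 in expectation.
#' @param known_frac Fraction of lncRNAs flagged "known" in the exported
#'   catalog.
#' @param caller_error_rate Per-transcript probability that one coding-
#'   potential caller disagrees in the exported calls.
#' @param n_chrom,chrom_length_bp Toy genome geometry.
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_pairs = 19,
                              n_unpaired_tumor = 0,
                              n_coding_genes = 500,
                              n_lncRNA = 300,
                              n_short_decoys = 10,
                              frac_de = 0.1,
                              frac_consistent = 0.7,
                              log2fc_mean = 2.0,
                              log2fc_sd = 0.5,
                              nb_dispersion = 0.1,
                              libsize_range = c(0.7, 1.3),
                              base_log2_mean = 5,
                              base_log2_sd = 2,
                              depth_factor = 8,
                              target_log2cpm_mean = 9,
                              target_log2cpm_sd = 0.5,
                              cis_window_bp = 100000,
                              n_cis_true = 1,
                              n_trans_true = 1,
                              trans_coupling = 2.5,
                              trans_latent_sd = 0.15,
                              known_frac = 0.8,
                              caller_error_rate = 0,
                              n_chrom = 4,
                              chrom_length_bp = 2e8,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pairs >= 2, cfg$n_unpaired_tumor >= 0,
            cfg$nb_dispersion > 0, length(cfg$libsize_range) == 2,
            cfg$libsize_range[1] > 0,
            cfg$libsize_range[1] <= cfg$libsize_range[2])
  for (f in c("frac_de", "frac_consistent", "known_frac",
              "caller_error_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("simulation config error: ", f, " must lie in [0, 1]")
  }
  structure(cfg, class = "SimulationConfig")
}

# Each transcript lives in its own genomic slot wide enough to hold its cis
# neighborhood (window plus decoy zone on both sides) without touching the
# next slot.
.slot_bp <- function(config) 2L * (3L * as.integer(config$cis_window_bp)) +
  110000L

#' Simulate a toy annotation with planted cis structure
#'
#' Populates toy chromosomes with protein-coding genes and lncRNA loci. Every
#' planted-DE lncRNA receives `n_cis_true` coding genes at a uniform random
#' distance in (0, window] and one decoy coding gene at a distance in
#' (window, 3 window]; all lncRNAs are longer than 200 nt and a handful of
#' short decoy transcripts is added.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation` (transcript records) and `truth` (planted
#'   ground-truth ledger: per-lncRNA effects and the target table).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_de <- round(config$frac_de * config$n_lncRNA)
  n_attached <- n_de * (config$n_cis_true + 1L)   # cis-true + one decoy each
  n_free_coding <- config$n_coding_genes - n_attached
  if (n_free_coding < n_de * config$n_trans_true)
    stop("generation error: not enough coding genes for planted targets")

  n_slots <- config$n_lncRNA + n_free_coding + config$n_short_decoys
  slot_bp <- .slot_bp(config)
  per_chrom <- floor(config$chrom_length_bp / slot_bp)
  if (n_slots > config$n_chrom * per_chrom)
    stop("generation error: chromosome overflow (", n_slots,
         " loci exceed capacity ", config$n_chrom * per_chrom, ")")

  slot_idx <- seq_len(n_slots)
  chrom <- paste0("chrS", ((slot_idx - 1L) %/% per_chrom) + 1L)
  slot_start <- (((slot_idx - 1L) %% per_chrom)) * slot_bp + 1L
  lnc_anchor <- 3L * as.integer(config$cis_window_bp) + 5000L

  w <- config$cis_window_bp
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncRNA))
  de_idx <- if (n_de > 0) sort(sample.int(config$n_lncRNA, n_de)) else integer(0)
  n_cons <- round(config$frac_consistent * n_de)
  cons_idx <- if (n_cons > 0) sort(sample(de_idx, n_cons)) else integer(0)

  # planted effects: signed magnitude, resampled until above the calling bound
  lfc <- numeric(config$n_lncRNA)
  if (n_de > 0) {
    mag <- abs(stats::rnorm(n_de, config$log2fc_mean, config$log2fc_sd))
    while (any(mag <= 1)) {
      bad <- mag <= 1
      mag[bad] <- abs(stats::rnorm(sum(bad), config$log2fc_mean,
                                   config$log2fc_sd))
    }
    lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }

  rec <- list()
  tgt <- list()

  # lncRNA loci, one slot each
  lnc_len <- sample(300:3000, config$n_lncRNA, replace = TRUE)
  lnc_start <- slot_start[seq_len(config$n_lncRNA)] + lnc_anchor
  rec[["lnc"]] <- data.frame(
    transcript_id = lnc_ids,
    gene_id = paste0("G_", lnc_ids),
    chrom = chrom[seq_len(config$n_lncRNA)],
    strand = sample(c("+", "-"), config$n_lncRNA, replace = TRUE),
    start = lnc_start,
    end = lnc_start + lnc_len - 1L,
    length_nt = lnc_len,
    biotype = "unclassified",
    stringsAsFactors = FALSE
  )

  place_near <- function(lnc_row, dist, gid) {
    len <- sample(1000:3000, 1L)
    side <- sample(c(-1L, 1L), 1L)
    if (side > 0) {
      gstart <- lnc_row$end + dist
      gend <- gstart + len - 1L
    } else {
      gend <- lnc_row$start - dist
      gstart <- gend - len + 1L
    }
    data.frame(transcript_id = gid, gene_id = paste0("G_", gid),
               chrom = lnc_row$chrom, strand = sample(c("+", "-"), 1L),
               start = gstart, end = gend, length_nt = len,
               biotype = "protein_coding", stringsAsFactors = FALSE)
  }

  # cis-true and decoy coding genes attached to planted-DE lncRNAs
  k <- 0L
  for (i in de_idx) {
    lr <- rec[["lnc"]][i, ]
    for (j in seq_len(config$n_cis_true)) {
      k <- k + 1L
      d <- sample.int(w, 1L)                      # (0, window]
      g <- place_near(lr, d, sprintf("PCG%04d", k))
      tgt[[length(tgt) + 1L]] <- data.frame(
        lnc_id = lr$transcript_id, gene_id = g$transcript_id,
        mode = "cis_true", distance_bp = d * sign(g$start - lr$start),
        stringsAsFactors = FALSE)
      rec[[paste0("cis", k)]] <- g
    }
    k <- k + 1L
    d <- w + sample.int(2L * w, 1L)               # (window, 3 window]
    g <- place_near(lr, d, sprintf("PCG%04d", k))
    tgt[[length(tgt) + 1L]] <- data.frame(
      lnc_id = lr$transcript_id, gene_id = g$transcript_id,
      mode = "cis_decoy", distance_bp = d * sign(g$start - lr$start),
      stringsAsFactors = FALSE)
    rec[[paste0("decoy", k)]] <- g
  }

  # remaining coding genes in their own slots
  free_ids <- sprintf("PCG%04d", n_attached + seq_len(n_free_coding))
  free_slot <- config$n_lncRNA + seq_len(n_free_coding)
  free_len <- sample(1000:3000, n_free_coding, replace = TRUE)
  free_start <- slot_start[free_slot] + sample.int(200000L, n_free_coding,
                                                   replace = TRUE)
  rec[["free"]] <- data.frame(
    transcript_id = free_ids, gene_id = paste0("G_", free_ids),
    chrom = chrom[free_slot], strand = sample(c("+", "-"), n_free_coding,
                                              replace = TRUE),
    start = free_start, end = free_start + free_len - 1L,
    length_nt = free_len, biotype = "protein_coding",
    stringsAsFactors = FALSE)

  # trans-true targets drawn from the free coding genes (genomic position
  # irrelevant by construction: they sit in distant slots)
  trans_pool <- free_ids
  for (i in de_idx) {
    pick <- trans_pool[seq_len(config$n_trans_true)]
    trans_pool <- setdiff(trans_pool, pick)
    for (g in pick) {
      tgt[[length(tgt) + 1L]] <- data.frame(
        lnc_id = lnc_ids[i], gene_id = g, mode = "trans_true",
        distance_bp = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  # short decoy transcripts (< 200 nt), rejected by the length rule
  if (config$n_short_decoys > 0) {
    sd_ids <- sprintf("SHORT%03d", seq_len(config$n_short_decoys))
    sd_slot <- config$n_lncRNA + n_free_coding + seq_len(config$n_short_decoys)
    sd_len <- sample(50:199, config$n_short_decoys, replace = TRUE)
    sd_start <- slot_start[sd_slot] + sample.int(200000L,
                                                 config$n_short_decoys,
                                                 replace = TRUE)
    rec[["short"]] <- data.frame(
      transcript_id = sd_ids, gene_id = paste0("G_", sd_ids),
      chrom = chrom[sd_slot],
      strand = sample(c("+", "-"), config$n_short_decoys, replace = TRUE),
      start = sd_start, end = sd_start + sd_len - 1L, length_nt = sd_len,
      biotype = "unclassified", stringsAsFactors = FALSE)
  }

  annotation <- do.call(rbind, c(rec, list(make.row.names = FALSE)))
  validate_annotation(annotation)

  is_de <- seq_len(config$n_lncRNA) %in% de_idx
  truth <- list(
    config = config,
    lnc = data.frame(
      transcript_id = lnc_ids,
      is_de = is_de,
      consistent = seq_len(config$n_lncRNA) %in% cons_idx,
      planted_log2fc = lfc,
      stringsAsFactors = FALSE),
    targets = if (length(tgt) > 0) do.call(rbind, tgt) else
      data.frame(lnc_id = character(0), gene_id = character(0),
                 mode = character(0), distance_bp = integer(0)),
    roles = data.frame(
      transcript_id = annotation$transcript_id,
      role = ifelse(grepl("^LNC", annotation$transcript_id), "lncRNA",
                    ifelse(grepl("^SHORT", annotation$transcript_id),
                           "short_decoy", "coding")),
      stringsAsFactors = FALSE),
    direction = NULL
  )
  list(annotation = annotation, truth = truth)
}

#' Simulate negative-binomial counts for a matched cohort
#'
#' Baseline per-transcript means are log2-normal; counts are negative
#' binomial with a common dispersion and per-sample library-size
#' multipliers. Planted-DE lncRNAs have their tumor mean scaled by
#' 2^(direction x |planted log2FC|) per pair; inconsistent lncRNAs flip
#' direction in `floor(n_pairs/3)` randomly chosen pairs. Planted cis- and
#' trans-true targets have their log2 mean tied to the lncRNA's realized
#' per-sample log2 expression through a shared latent factor plus Gaussian
#' noise, so the realized correlation on log2(CPM+1) exceeds 0.95 in
#' expectation at the default coupling.
#'
#' @param annotation,truth Output of [simulate_annotation()].
#' @param config The same [simulation_config()].
#' @return List with `cohort` (a `PairedCohort`) and the completed `truth`
#'   (per-pair direction matrix filled in).
#' @export
simulate_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)

  pair_ids <- sprintf("P%02d", seq_len(config$n_pairs))
  samples <- data.frame(
    sample_id = c(paste0(pair_ids, "_T"), paste0(pair_ids, "_N"),
                  if (config$n_unpaired_tumor > 0)
                    sprintf("U%02d_T", seq_len(config$n_unpaired_tumor))),
    condition = c(rep("tumor", config$n_pairs),
                  rep("normal", config$n_pairs),
                  rep("tumor", config$n_unpaired_tumor)),
    pair_id = c(pair_ids, pair_ids, rep(NA_character_,
                                        config$n_unpaired_tumor)),
    stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  tx <- annotation$transcript_id
  n_t <- length(tx)

  libmult <- stats::runif(n_s, config$libsize_range[1],
                          config$libsize_range[2])

  base_log2 <- stats::rnorm(n_t, config$base_log2_mean, config$base_log2_sd)

  # per-pair direction matrix for planted lncRNAs
  dir_mat <- matrix(0L, nrow = nrow(truth$lnc), ncol = config$n_pairs,
                    dimnames = list(truth$lnc$transcript_id, pair_ids))
  n_flip <- floor(config$n_pairs / 3)
  for (i in which(truth$lnc$is_de)) {
    base_dir <- sign(truth$lnc$planted_log2fc[i])
    dirs <- rep(base_dir, config$n_pairs)
    if (!truth$lnc$consistent[i] && n_flip > 0)
      dirs[sample.int(config$n_pairs, n_flip)] <- -base_dir
    dir_mat[i, ] <- as.integer(dirs)
  }

  # log2 fold applied to tumor columns, per transcript x sample
  fc_log2 <- matrix(0, nrow = n_t, ncol = n_s,
                    dimnames = list(tx, samples$sample_id))
  tumor_col <- samples$condition == "tumor"
  for (i in which(truth$lnc$is_de)) {
    id <- truth$lnc$transcript_id[i]
    mag <- abs(truth$lnc$planted_log2fc[i])
    for (p in seq_along(pair_ids)) {
      sc <- samples$pair_id == pair_ids[p] & tumor_col
      sc[is.na(sc)] <- FALSE
      fc_log2[id, sc] <- dir_mat[i, p] * mag
    }
    if (config$n_unpaired_tumor > 0) {
      un <- is.na(samples$pair_id)
      fc_log2[id, un] <- sign(truth$lnc$planted_log2fc[i]) * mag
    }
  }

  size <- 1 / config$nb_dispersion
  draw_nb <- function(mu) {
    matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }

  mu_base <- config$depth_factor * 2^(base_log2 + fc_log2) *
    matrix(libmult, nrow = n_t, ncol = n_s, byrow = TRUE)
  dimnames(mu_base) <- list(tx, samples$sample_id)

  # first pass: everything except planted targets
  counts <- draw_nb(mu_base)

  # second pass: planted targets coupled to their lncRNA's realized
  # log2 CPM through a shared latent factor. Target abundance is set on
  # the CPM scale against the library of the non-target transcripts, so a
  # coupled swing stays a bounded (small) fraction of the library and CPM
  # normalization cannot cancel the planted signal.
  tgt_rows <- truth$targets[truth$targets$mode %in% c("cis_true",
                                                      "trans_true"), ,
                            drop = FALSE]
  if (nrow(tgt_rows) > 0) {
    tgt_gene <- unique(tgt_rows$gene_id)
    lib_prov <- colSums(counts[!tx %in% tgt_gene, , drop = FALSE])
    base_cpm <- stats::rnorm(length(tgt_gene), config$target_log2cpm_mean,
                             config$target_log2cpm_sd)
    names(base_cpm) <- tgt_gene
    for (r in seq_len(nrow(tgt_rows))) {
      lnc <- tgt_rows$lnc_id[r]
      gid <- tgt_rows$gene_id[r]
      l_cpm <- log2(1e6 * counts[lnc, ] / lib_prov + 1)
      # standardized and winsorized latent factor: the loading is per SD of
      # the lncRNA's realized expression, which equalizes the planted
      # correlation across effect sizes and bounds the target's dynamic
      # range (no single target can swamp the library)
      z <- (l_cpm - mean(l_cpm)) / stats::sd(l_cpm)
      z <- pmax(pmin(z, 1.5), -1.5)
      latent <- config$trans_coupling * z +
        stats::rnorm(n_s, 0, config$trans_latent_sd)
      cpm_g <- 2^(base_cpm[gid] + latent)
      counts[gid, ] <- stats::rnbinom(n_s, mu = cpm_g * lib_prov / 1e6,
                                      size = size)
    }
  }

  mode(counts) <- "integer"
  truth$direction <- dir_mat
  list(cohort = paired_cohort(counts, samples, annotation), truth = truth)
}

#' Simulate a full synthetic cohort in one call
#' @param config A [simulation_config()].
#' @return List with `cohort`, `annotation` and `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  cx <- simulate_counts(ann$annotation, ann$truth, config)
  list(cohort = cx$cohort, annotation = ann$annotation, truth = cx$truth)
}

#' Export a synthetic cohort as an on-disk fixture directory
#'
#' Writes the six files every downstream reader consumes: `annotation.gtf`,
#' `counts.tsv`, `samples.tsv`, `known_catalog.txt` (a seeded random subset
#' of the lncRNAs flagged known), `coding_calls.tsv` (true lncRNAs called
#' non-coding by all three callers, coding genes called coding, with a
#' configurable per-row disagreement rate) and `truth.tsv`.
#'
#' @param cohort A `PairedCohort` from [simulate_counts()].
#' @param truth The matching truth ledger (carries the config).
#' @param directory Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
export_fixture <- function(cohort, truth, directory) {
  config <- truth$config
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  p <- function(f) file.path(directory, f)

  write_gtf(cohort$annotation, p("annotation.gtf"))
  cm <- data.frame(transcript_id = rownames(cohort$counts),
                   cohort$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(cm, p("counts.tsv"))
  write_table(cohort$samples, p("samples.tsv"))

  lnc_ids <- truth$roles$transcript_id[truth$roles$role == "lncRNA"]
  n_known <- round(config$known_frac * length(lnc_ids))
  known <- sort(sample(lnc_ids, n_known))
  writeLines(known, p("known_catalog.txt"))

  roles <- truth$roles
  is_coding <- roles$role == "coding"
  calls <- matrix(rep(is_coding, 3), ncol = 3)
  if (config$caller_error_rate > 0) {
    err <- stats::runif(nrow(roles)) < config$caller_error_rate
    which_caller <- sample.int(3L, nrow(roles), replace = TRUE)
    for (i in which(err)) calls[i, which_caller[i]] <- !calls[i, which_caller[i]]
  }
  cc <- data.frame(transcript_id = roles$transcript_id,
                   caller_1 = tolower(calls[, 1]),
                   caller_2 = tolower(calls[, 2]),
                   caller_3 = tolower(calls[, 3]),
                   stringsAsFactors = FALSE)
  write_table(cc, p("coding_calls.tsv"))

  tr <- merge(truth$roles, truth$lnc, by = "transcript_id", all.x = TRUE,
              sort = FALSE)
  tr <- tr[match(truth$roles$transcript_id, tr$transcript_id), ]
  tr$directions <- NA_character_
  if (!is.null(truth$direction)) {
    hit <- match(rownames(truth$direction), tr$transcript_id)
    tr$directions[hit] <- apply(truth$direction, 1, paste, collapse = ";")
  }
  tg <- truth$targets
  tr$target_of <- NA_character_
  tr$target_mode <- NA_character_
  tr$target_distance_bp <- NA_integer_
  if (nrow(tg) > 0) {
    hit <- match(tg$gene_id, tr$transcript_id)
    tr$target_of[hit] <- tg$lnc_id
    tr$target_mode[hit] <- tg$mode
    tr$target_distance_bp[hit] <- tg$distance_bp
  }
  write_table(tr, p("truth.tsv"))

  invisible(vapply(c("annotation.gtf", "counts.tsv", "samples.tsv",
                     "known_catalog.txt", "coding_calls.tsv", "truth.tsv"),
                   p, character(1)))
}
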