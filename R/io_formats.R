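# Valid biotype labels carried on transcript records throughout the package.
.BIOTYPES <- c("protein_coding", "lncRNA_known", "lncRNA_novel_candidate",
               "unclassified")

#' Read transcript records from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF (1-based, inclusive coordinates) and returns
#' one record per `transcript` feature. When `exon` children are present the
#' transcript length is the sum of exon lengths (spliced length); otherwise it
#' is the genomic span `end - start + 1`. Coordinates are never shifted: the
#' GTF convention is the package's internal convention.
#'
#' @param path Path to a GTF file (plain or gzip).
#' @return A data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`+`, `-` or `.`), `start`, `end`, `length_nt`, `biotype`.
#'   Biotype is taken from the `transcript_biotype` attribute when it matches
#'   one of `protein_coding`, `lncRNA_known`, `lncRNA_novel_candidate`,
#'   otherwise `unclassified`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id") %in% colnames(meta)))
    stop("GTF parse error: no transcript_id attribute found in ", path)
  if (!"gene_id" %in% colnames(meta))
    stop("GTF parse error: no gene_id attribute found in ", path)

  is_tx <- as.character(meta$type) == "transcript"
  is_exon <- as.character(meta$type) == "exon"
  if (!any(is_tx)) stop("GTF parse error: no transcript features in ", path)

  tx_id <- as.character(meta$transcript_id[is_tx])
  gene_id <- as.character(meta$gene_id[is_tx])
  bad <- which(is.na(tx_id) | tx_id == "" | is.na(gene_id) | gene_id == "")
  if (length(bad) > 0)
    stop("GTF parse error: transcript feature #", bad[1],
         " lacks a transcript_id or gene_id attribute")
  if (anyDuplicated(tx_id))
    stop("GTF validation error: duplicated transcript_id: ",
         tx_id[duplicated(tx_id)][1])

  tx <- gr[is_tx]
  rec <- data.frame(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(tx))),
    start = GenomicRanges::start(tx),
    end = GenomicRanges::end(tx),
    stringsAsFactors = FALSE
  )
  if (any(rec$end < rec$start))
    stop("GTF validation error: end < start for transcript ",
         rec$transcript_id[which(rec$end < rec$start)[1]])

  # spliced length from exon children where present, else span
  rec$length_nt <- rec$end - rec$start + 1L
  if (any(is_exon)) {
    ex_id <- as.character(meta$transcript_id[is_exon])
    ex_len <- GenomicRanges::width(gr[is_exon])
    spliced <- tapply(ex_len, ex_id, sum)
    hit <- rec$transcript_id %in% names(spliced)
    rec$length_nt[hit] <- as.integer(spliced[rec$transcript_id[hit]])
  }

  bt <- rep("unclassified", nrow(rec))
  if ("transcript_biotype" %in% colnames(meta)) {
    raw_bt <- as.character(meta$transcript_biotype[is_tx])
    ok <- !is.na(raw_bt) & raw_bt %in% .BIOTYPES
    bt[ok] <- raw_bt[ok]
  }
  rec$biotype <- bt
  validate_annotation(rec)
  rec
}

#' Write transcript records to a GTF file
#'
#' Inverse of [read_gtf()] for span-level records (one `transcript` line per
#' record, no exon children). Coordinates are written exactly as stored.
#'
#' @param annotation Data.frame of transcript records (see [read_gtf()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(annotation, path) {
  validate_annotation(annotation)
  strand <- sub("^\\.$", "*", annotation$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lncrecur",
    type = "transcript",
    transcript_id = annotation$transcript_id,
    gene_id = annotation$gene_id,
    transcript_biotype = annotation$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

validate_annotation <- function(annotation) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
            "length_nt", "biotype")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0)
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$transcript_id))
    stop("annotation validation error: duplicated transcript_id")
  if (any(annotation$start < 1))
    stop("annotation validation error: start < 1")
  if (any(annotation$end < annotation$start))
    stop("annotation validation error: end < start")
  if (any(annotation$length_nt < 1))
    stop("annotation validation error: length_nt < 1")
  if (any(annotation$length_nt > annotation$end - annotation$start + 1))
    stop("annotation validation error: spliced length exceeds span")
  invisible(annotation)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `condition` (`tumor`/`normal`)
#'   and `pair_id`. An empty or `NA` pair_id marks the sample as unpaired:
#'   unpaired samples take part in correlation (trans-target) analysis only,
#'   never in paired differential expression.
#' @return A validated data.frame with those three columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c("sample_id", "condition", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  df$pair_id <- as.character(df$pair_id)
  validate_sample_sheet(df[, need])
}

validate_sample_sheet <- function(samples) {
  if (anyDuplicated(samples$sample_id))
    stop("sample sheet validation error: duplicated sample_id")
  bad_cond <- !samples$condition %in% c("tumor", "normal")
  if (any(bad_cond))
    stop("sample sheet validation error: condition must be tumor/normal, got ",
         samples$condition[which(bad_cond)[1]])
  paired <- samples[!is.na(samples$pair_id), , drop = FALSE]
  if (nrow(paired) > 0) {
    for (pid in unique(paired$pair_id)) {
      sub <- paired[paired$pair_id == pid, , drop = FALSE]
      if (nrow(sub) != 2 || !setequal(sub$condition, c("tumor", "normal")))
        stop("sample sheet validation error: pair ", pid,
             " must have exactly one tumor and one normal sample")
    }
  }
  samples
}

#' Assemble a paired cohort from counts, samples and annotation
#'
#' @param counts Non-negative integer matrix, rows named by transcript id,
#'   columns named by sample id.
#' @param samples Sample sheet data.frame (see [read_sample_sheet()]).
#' @param annotation Transcript records covering every row of `counts`.
#' @return An object of class `PairedCohort`: a list with elements `counts`,
#'   `samples`, `annotation`.
#' @export
paired_cohort <- function(counts, samples, annotation) {
  counts <- as.matrix(counts)
  validate_annotation(annotation)
  validate_sample_sheet(samples)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("cohort validation error: counts must have row and column names")
  if (any(is.na(counts)))
    stop("cohort validation error: counts contain NA")
  if (any(counts < 0))
    stop("cohort validation error: negative count")
  if (any(counts != round(counts)))
    stop("cohort validation error: non-integer count")
  if (!all(rownames(counts) %in% annotation$transcript_id))
    stop("cohort validation error: count rows absent from annotation: ",
         paste(utils::head(setdiff(rownames(counts),
                                   annotation$transcript_id), 5),
               collapse = ", "))
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("cohort validation error: count columns absent from sample sheet: ",
         paste(utils::head(setdiff(colnames(counts), samples$sample_id), 5),
               collapse = ", "))
  structure(list(counts = counts, samples = samples, annotation = annotation),
            class = "PairedCohort")
}

#' @export
print.PairedCohort <- function(x, ...) {
  np <- length(cohort_pairs(x))
  cat("PairedCohort:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples (", np, "matched pairs )\n")
  invisible(x)
}

#' Matched pair identifiers of a cohort
#' @param cohort A `PairedCohort`.
#' @return Character vector of pair ids (possibly empty).
#' @export
cohort_pairs <- function(cohort) {
  pid <- cohort$samples$pair_id
  sort(unique(pid[!is.na(pid)]))
}

#' Read a count matrix plus sample sheet into a PairedCohort
#'
#' Rows of the matrix whose transcript id is absent from `annotation` are
#' dropped with a warning naming them; everything else is validated strictly
#' (integer, non-negative, matched pair structure).
#'
#' @param matrix_path TSV: header row of sample ids, first column of
#'   transcript ids.
#' @param sheet_path Sample sheet TSV.
#' @param annotation Transcript records from [read_gtf()].
#' @return A `PairedCohort`.
#' @export
read_counts <- function(matrix_path, sheet_path, annotation) {
  if (!file.exists(matrix_path)) stop("count matrix not found: ", matrix_path)
  samples <- read_sample_sheet(sheet_path)
  df <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("cohort validation error: non-numeric count value")
  rownames(mat) <- ids
  unknown <- setdiff(ids, annotation$transcript_id)
  if (length(unknown) > 0) {
    warning("dropping ", length(unknown),
            " count rows absent from annotation: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    mat <- mat[!ids %in% unknown, , drop = FALSE]
  }
  storage_ok <- all(mat == round(mat)) && !any(mat < 0)
  if (!storage_ok) stop("cohort validation error: counts must be non-negative integers")
  mode(mat) <- "integer"
  paired_cohort(mat, samples, annotation)
}

#' Write a result table as TSV
#'
#' Fixed column order (the data.frame's own), floats rendered with 6
#' significant digits, `NA` as the sole missing-value token. Round-trips
#' through [read_result_table()] losslessly at that precision.
#'
#' @param records A data.frame (may have zero rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- signif(out[[j]], 6)
      out[[j]][is.nan(out[[j]])] <- NA_real_   # "NA" is the sole NA token
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path TSV path.
#' @return A data.frame with `NA` restored.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

#' Read a known-lncRNA catalog (one id per line)
#' @param path Plain-text file of transcript ids.
#' @return Character vector of unique ids.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path)
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}

#' Read coding-potential calls from three external callers
#'
#' @param path TSV with columns `transcript_id`, `caller_1`, `caller_2`,
#'   `caller_3`; each call is `true`/`false` where `true` means "predicted
#'   coding".
#' @return Data.frame with a character id column and three logical columns.
#' @export
read_coding_calls <- function(path) {
  if (!file.exists(path)) stop("coding calls not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "caller_1", "caller_2", "caller_3")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("coding calls lack columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("coding calls validation error: duplicate call rows for ",
         df$transcript_id[duplicated(df$transcript_id)][1])
  for (cl in need[-1]) {
    v <- tolower(as.character(df[[cl]]))
    if (!all(v %in% c("true", "false")))
      stop("coding calls validation error: ", cl, " must be true/false")
    df[[cl]] <- v == "true"
  }
  df[, need]
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT parse error: line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("GMT parse error: duplicated set id")
  sets
}
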