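# Readers and writers for every on-disk format the pipeline touches.
#
# On-disk interval formats are BED-dialect 0-based half-open; CpG positions
# are 0-based positions of the C of the CpG dinucleotide.  In memory,
# intervals live in GRanges (1-based closed), converted exactly once here.

#' Read a sample sheet
#'
#' A sample sheet is a TSV with columns `sample`, `population` and `assay`.
#' Populations must come from the recognised B-cell lineage / tumor set
#' (HPC, EarlyB, NBC-B, NBC-T, GCBC, MBC, PB/PC, cMCL, nnMCL); assays from
#' methylation, segmentation, accessibility, rnaseq.  (sample, assay) pairs
#' must be unique.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns sample, population, assay.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character"))
  need <- c("sample", "population", "assay")
  if (!all(need %in% names(df)))
    stop_format("sample sheet %s must have columns %s", path,
                paste(need, collapse = ", "))
  bad_pop <- setdiff(unique(df$population), POPULATIONS)
  if (length(bad_pop))
    stop_format("unknown population(s): %s", paste(bad_pop, collapse = ", "))
  bad_assay <- setdiff(unique(df$assay), ASSAYS)
  if (length(bad_assay))
    stop_format("unknown assay(s): %s", paste(bad_assay, collapse = ", "))
  key <- paste(df$sample, df$assay)
  if (anyDuplicated(key))
    stop_format("duplicated (sample, assay) pair: %s", key[duplicated(key)][1])
  df[, need]
}

#' Write a sample sheet
#' @param sheet data.frame with columns sample, population, assay.
#' @param path Output TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a beta-value methylation matrix
#'
#' TSV with probe ids in the first column and one column per sample.  All
#' present values must lie in `[0, 1]`; missing values (`NA`) are preserved.
#' If a sample sheet is given, every matrix column must be a known
#' methylation sample.
#'
#' @param path Path to the TSV file.
#' @param sample_sheet Optional sample sheet (see [read_sample_sheet()]).
#' @return Numeric matrix (CpG x sample) with probe-id rownames.
#' @export
read_beta_matrix <- function(path, sample_sheet = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop_format("duplicated probe id: %s", ids[duplicated(ids)][1])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop_format("non-numeric values in beta matrix %s", path)
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop_format("beta value %.4g outside [0,1] at probe %s, sample %s",
                m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                colnames(m)[bad[1, 2]])
  if (!is.null(sample_sheet)) {
    meth <- sample_sheet$sample[sample_sheet$assay == "methylation"]
    unknown <- setdiff(colnames(m), meth)
    if (length(unknown))
      stop_format("beta matrix column(s) not in sample sheet: %s",
                  paste(unknown, collapse = ", "))
  }
  m
}

#' Write a beta-value matrix
#'
#' Values are written with full (round-trippable) precision, so that
#' write-then-read is the identity.
#'
#' @param beta Numeric matrix with probe-id rownames.
#' @param path Output TSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  df <- data.frame(probe_id = rownames(beta),
                   apply(beta, 2, format, digits = 17, trim = TRUE,
                         scientific = FALSE),
                   check.names = FALSE)
  df[df == "NA"] <- NA
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a CpG probe table
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (0-based position of the C of
#' the CpG dinucleotide).  Ids must be unique and positions non-negative.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns probe_id, chrom, pos.
#' @export
read_cpg_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop_format("CpG table %s must have columns %s", path,
                paste(need, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop_format("duplicated probe id in %s", path)
  if (any(df$pos < 0)) stop_format("negative CpG position in %s", path)
  df
}

#' Read a 12-state chromatin segmentation
#'
#' BED-like 4-column file (chrom, start, end, state) with states `E1`..`E12`
#' at (typically) 200-bp resolution, 0-based half-open coordinates.
#' Intervals must be non-overlapping per chromosome; gaps are allowed and
#' detectable (positions not covered by any interval).
#'
#' @param path Path to the BED-like file.
#' @return A `GRanges` with a `state` metadata column.
#' @export
read_segmentation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 4) stop_format("segmentation %s needs 4 columns", path)
  state <- as.character(dt[[4]])
  bad <- setdiff(unique(state), CHROM_STATES)
  if (length(bad))
    stop_format("unknown chromatin state '%s' in %s", bad[1], path)
  gr <- GenomicRanges::GRanges(as.character(dt[[1]]),
                               IRanges::IRanges(start = dt[[2]] + 1L,
                                                end = dt[[3]]))
  mcols(gr)$state <- state
  if (!IRanges::isDisjoint(gr))
    stop_format("overlapping segmentation intervals in %s", path)
  sort(gr)
}

#' Write a segmentation track to a BED-like file
#' @param seg `GRanges` with a `state` column.
#' @param path Output path.
#' @export
write_segmentation <- function(seg, path) {
  data.table::fwrite(
    data.frame(chrom = as.character(GenomicRanges::seqnames(seg)),
               start = GenomicRanges::start(seg) - 1L,
               end = GenomicRanges::end(seg),
               state = mcols(seg)$state),
    path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ peak file into GRanges
#'
#' @param path BED path (0-based half-open on disk).
#' @param name_col If `TRUE`, keep column 4 as metadata column `name`
#'   (used for ReMap-style files where column 4 carries the TF name).
#' @return A `GRanges`.
#' @export
read_bed_peaks <- function(path, name_col = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3) stop_format("BED file %s needs >= 3 columns", path)
  if (any(dt[[2]] < 0) || any(dt[[3]] <= dt[[2]]))
    stop_format("invalid interval in %s (need 0 <= start < end)", path)
  gr <- GenomicRanges::GRanges(as.character(dt[[1]]),
                               IRanges::IRanges(start = dt[[2]] + 1L,
                                                end = dt[[3]]))
  if (name_col) {
    if (ncol(dt) < 4) stop_format("BED file %s has no name column", path)
    mcols(gr)$name <- as.character(dt[[4]])
  }
  gr
}

#' Write GRanges as BED
#' @param gr A `GRanges`; if a `name` column is present it is written as
#'   BED column 4.
#' @param path Output path.
#' @export
write_bed_peaks <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(mcols(gr)$name)) df$name <- mcols(gr)$name
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a header line `>ID NAME` followed by four
#' rows of non-negative counts for A, C, G and T (with or without the
#' bracketed `A [ ... ]` decoration).  Each PFM must be 4 x L with L >= 4
#' and positive column sums.
#'
#' @param path Path to the JASPAR text file.
#' @return Named list of 4 x L count matrices (rownames A,C,G,T) with
#'   attributes `id` and `tf`.
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_format("no PFM headers in %s", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    tf <- if (length(parts) > 1) parts[2] else parts[1]
    last <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    body <- lines[seq(starts[i] + 1L, length.out = max(0, last - starts[i]))]
    if (length(body) < 4) stop_format("PFM %s: empty or truncated block", id)
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]", "", trimws(l))
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v) || !length(v))
        stop_format("PFM %s: unparseable count row", id)
      v
    })
    len <- unique(vapply(rows, length, 1L))
    if (length(len) != 1)
      stop_format("PFM %s: rows of unequal length", id)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop_format("PFM %s: negative count", id)
    if (ncol(m) < 4) stop_format("PFM %s: width %d < 4", id, ncol(m))
    if (any(colSums(m) <= 0)) stop_format("PFM %s: zero-sum column", id)
    attr(m, "id") <- id
    attr(m, "tf") <- tf
    out[[id]] <- m
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pfms Named list of 4 x L matrices with `id`/`tf` attributes.
#' @param path Output path.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pfms) {
    writeLines(sprintf(">%s %s", attr(m, "id"), attr(m, "tf")), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a gene-model table
#'
#' One row per transcript.  Required columns: `transcript_id`, `gene_id`,
#' `chrom`, `strand` (+/-), `start`, `end` (0-based half-open transcript
#' span), `exon_starts`, `exon_ends` (comma-separated, 0-based half-open),
#' `coding` (0/1).  Optional `cds_start`, `cds_end` (0-based half-open CDS
#' span) are required to derive UTR annotations for coding transcripts.
#'
#' @param path Path to the TSV file.
#' @return data.frame with list-columns `exon_starts`/`exon_ends` holding
#'   integer vectors.
#' @export
read_gene_models <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends", "coding")
  if (!all(need %in% names(df)))
    stop_format("gene model table %s must have columns %s", path,
                paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop_format("gene model strand must be + or -")
  parse_csv <- function(x) lapply(strsplit(as.character(x), ","),
                                  function(v) as.integer(v))
  df$exon_starts <- parse_csv(df$exon_starts)
  df$exon_ends <- parse_csv(df$exon_ends)
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es))
      stop_format("transcript %s: malformed exon list", df$transcript_id[i])
    if (min(es) < df$start[i] || max(ee) > df$end[i])
      stop_format("transcript %s: exon outside transcript span",
                  df$transcript_id[i])
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop_format("transcript %s: exons unsorted or overlapping",
                  df$transcript_id[i])
  }
  if (!all(c("cds_start", "cds_end") %in% names(df))) {
    df$cds_start <- NA_integer_
    df$cds_end <- NA_integer_
  }
  df
}

#' Write a gene-model table
#' @param models data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  out <- models
  out$exon_starts <- vapply(models$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(models$exon_ends, paste, "", collapse = ",")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Collapse transcript models to gene level
#'
#' Gene span is the union of its transcript spans; the TSS is the
#' strand-aware 5' extreme (minimum start on `+`, maximum end minus one on
#' `-`), in 0-based coordinates.
#'
#' @param models Transcript table from [read_gene_models()].
#' @param coding_only Keep protein-coding genes only (default TRUE, matching
#'   closest-gene assignment which is restricted to protein-coding genes).
#' @return data.frame with columns gene_id, chrom, strand, start, end, tss.
#' @export
gene_level_models <- function(models, coding_only = TRUE) {
  if (coding_only) models <- models[models$coding == 1, , drop = FALSE]
  if (!nrow(models)) stop_format("no gene models left after coding filter")
  sp <- split(seq_len(nrow(models)), models$gene_id)
  rows <- lapply(sp, function(idx) {
    strand <- unique(models$strand[idx])
    chrom <- unique(models$chrom[idx])
    if (length(strand) != 1 || length(chrom) != 1)
      stop_format("gene %s has inconsistent strand/chrom",
                  models$gene_id[idx[1]])
    s <- min(models$start[idx]); e <- max(models$end[idx])
    data.frame(gene_id = models$gene_id[idx[1]], chrom = chrom,
               strand = strand, start = s, end = e,
               tss = if (strand == "+") s else e - 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Read an RNA-seq count matrix
#'
#' TSV with gene ids in the first column; values must be non-negative.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (gene x sample).
#' @export
read_counts_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE))
    stop_format("negative count in %s", path)
  m
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)
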