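# Internal helpers shared across modules.

#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Chromatin states emitted by the 12-state segmentation.
CHROM_STATES <- paste0("E", 1:12)

# Cell populations recognised in sample sheets.
POPULATIONS <- c("HPC", "EarlyB", "NBC-B", "NBC-T", "GCBC", "MBC", "PB/PC",
                 "cMCL", "nnMCL")

ASSAYS <- c("methylation", "segmentation", "accessibility", "rnaseq")

# Hierarchical chromatin categories, in priority order, and the merged set.
HIER_CATEGORIES <- c("ActivePromoter", "ActiveTranscription", "ActiveEnhancer",
                     "Other", "Primed", "Inactive")
MERGED_CATEGORIES <- c("Active", "Other", "Primed", "Inactive")

# Genic annotation classes used by the fractionated score.
ANNOTATION_CLASSES <- c("intergenic", "upstream_1to5kb", "promoter",
                        "five_utr", "first_exon", "exon", "intron",
                        "three_utr")

EXPRESSION_CATEGORIES <- c("not expressed", "stable expression",
                           "lost expression", "downregulated",
                           "de novo expression", "upregulated")

`%||%` <- function(a, b) if (is.null(a)) b else a

mi_log <- function(stage, ...) {
  message(sprintf("[methimprint:%s] %s", stage, paste0(...)))
}

#' Derive a deterministic child seed from a master seed
#'
#' Each pipeline stage and each synthetic-data component draws its randomness
#' from its own child seed, so stages can be re-run in isolation with
#' identical results and adding a component does not perturb the others.
#'
#' @param master Integer master seed.
#' @param k Integer component index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(k), length(k) == 1L)
  as.integer((abs(as.numeric(master)) * 7919 + as.numeric(k) * 104729 + 17) %%
               2147483646)
}

# Point GRanges from 0-based CpG positions (converted once, at the boundary).
cpg_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L,
                                                 width = 1L))
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
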