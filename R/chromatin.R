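# Stage 2: hierarchical chromatin-state categories per population,
# accessibility split, fractionated genic-annotation scores, and category
# enrichment.

# Priority-ordered rule table: first rule whose state set intersects the
# per-sample states wins; no match => Inactive.
HIERARCHY_RULES <- list(
  ActivePromoter = "E1",
  ActiveTranscription = "E7",
  ActiveEnhancer = c("E2", "E6"),
  Other = c("E3", "E4", "E9"),
  Primed = "E5"
)

#' Chromatin state at a genomic position
#'
#' @param segmentation `GRanges` segmentation track (see
#'   [read_segmentation()]).
#' @param chrom,pos Contig and 0-based position(s).
#' @param probe_id Optional id(s) used in error messages.
#' @return Character vector of states (`E1`..`E12`).  An uncovered position
#'   is an error naming the probe.
#' @export
state_at_position <- function(segmentation, chrom, pos, probe_id = NULL) {
  pts <- cpg_granges(chrom, pos)
  hits <- GenomicRanges::findOverlaps(pts, segmentation)
  out <- rep(NA_character_, length(pts))
  out[queryHits(hits)] <- mcols(segmentation)$state[subjectHits(hits)]
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    id <- if (!is.null(probe_id)) probe_id[i] else
      sprintf("%s:%d", chrom[i], pos[i])
    stop_format("position not covered by segmentation: %s", id)
  }
  out
}

#' Hierarchical chromatin category from per-sample states
#'
#' Applies the priority rules: any sample in E1 gives ActivePromoter; else
#' any E7 gives ActiveTranscription; else any E2/E6 gives ActiveEnhancer;
#' else any of E3, E4, E9 gives Other; else any E5 gives Primed; otherwise
#' Inactive.  Active annotations therefore always dominate inactive ones.
#'
#' @param per_sample_states Character vector of states (one per sample of
#'   the population).
#' @return A single category string.
#' @export
classify_population_state <- function(per_sample_states) {
  if (!length(per_sample_states)) stop_format("empty state set")
  bad <- setdiff(per_sample_states, CHROM_STATES)
  if (length(bad)) stop_format("unknown chromatin state: %s", bad[1])
  for (cat in names(HIERARCHY_RULES)) {
    if (any(per_sample_states %in% HIERARCHY_RULES[[cat]])) return(cat)
  }
  "Inactive"
}

# Vectorised hierarchy over a CpG x sample state matrix.
classify_state_matrix <- function(state_mat) {
  bad <- setdiff(unique(as.vector(state_mat)), CHROM_STATES)
  if (length(bad)) stop_format("unknown chromatin state: %s", bad[1])
  out <- rep("Inactive", nrow(state_mat))
  undecided <- rep(TRUE, nrow(state_mat))
  for (cat in names(HIERARCHY_RULES)) {
    hit <- rowSums(matrix(state_mat %in% HIERARCHY_RULES[[cat]],
                          nrow(state_mat))) > 0
    out[undecided & hit] <- cat
    undecided <- undecided & !hit
  }
  out
}

#' Merge the three active categories into one
#'
#' @param category Hierarchical category (vectorised).
#' @return Merged category: Active, Other, Primed or Inactive.
#' @export
merge_active <- function(category) {
  bad <- setdiff(unique(category), HIER_CATEGORIES)
  if (length(bad)) stop_format("unknown category: %s", bad[1])
  ifelse(category %in% c("ActivePromoter", "ActiveTranscription",
                         "ActiveEnhancer"), "Active", category)
}

#' Split CpGs by chromatin accessibility
#'
#' A CpG is accessible iff its position lies within at least one peak.
#' Active CpGs are refined into ActiveAccessible / ActiveInaccessible;
#' non-Active CpGs keep their category and carry the flag for reporting.
#'
#' @param chrom,pos Contig names and 0-based CpG positions.
#' @param category Merged categories (Active/Other/Primed/Inactive).
#' @param peaks `GRanges` of accessibility peaks.
#' @return data.frame with `accessible` flag and `refined` category.
#' @export
split_by_accessibility <- function(chrom, pos, category, peaks) {
  pts <- cpg_granges(chrom, pos)
  accessible <- GenomicRanges::countOverlaps(pts, peaks) > 0
  refined <- ifelse(category == "Active",
                    ifelse(accessible, "ActiveAccessible",
                           "ActiveInaccessible"),
                    category)
  data.frame(accessible = accessible, refined = refined)
}

# Build per-transcript annotation intervals as a GRanges with an `annot`
# column.  All arithmetic on the 0-based half-open disk convention, then
# converted to 1-based closed at the end.  Promoter = <1 kb upstream of the
# TSS, upstream_1to5kb = 1-5 kb upstream, both strand-aware.
build_annotation_ranges <- function(models) {
  ch <- character(0); s0 <- integer(0); e0 <- integer(0); an <- character(0)
  add <- function(chrom, start0, end0, annot) {
    start0 <- pmax(start0, 0L)
    keep <- end0 > start0
    ch <<- c(ch, rep(chrom, sum(keep)))
    s0 <<- c(s0, as.integer(start0[keep]))
    e0 <<- c(e0, as.integer(end0[keep]))
    an <<- c(an, rep(annot, sum(keep)))
  }
  for (i in seq_len(nrow(models))) {
    chrom <- models$chrom[i]; strand <- models$strand[i]
    ts <- models$start[i]; te <- models$end[i]
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    if (strand == "+") {
      add(chrom, ts - 1000L, ts, "promoter")
      add(chrom, ts - 5000L, ts - 1000L, "upstream_1to5kb")
      first <- 1L
    } else {
      add(chrom, te, te + 1000L, "promoter")
      add(chrom, te + 1000L, te + 5000L, "upstream_1to5kb")
      first <- length(es)
    }
    add(chrom, es[first], ee[first], "first_exon")
    for (k in seq_along(es)) add(chrom, es[k], ee[k], "exon")
    if (length(es) > 1)
      for (k in seq_len(length(es) - 1L))
        add(chrom, ee[k], es[k + 1L], "intron")
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    if (!is.na(cs) && !is.na(ce)) {
      # UTRs: exonic sequence outside the CDS span, 5'/3' by strand
      for (k in seq_along(es)) {
        lo <- es[k]; hi <- ee[k]
        left_lo <- lo; left_hi <- min(hi, cs)      # exonic part before CDS
        right_lo <- max(lo, ce); right_hi <- hi    # exonic part after CDS
        if (strand == "+") {
          add(chrom, left_lo, left_hi, "five_utr")
          add(chrom, right_lo, right_hi, "three_utr")
        } else {
          add(chrom, left_lo, left_hi, "three_utr")
          add(chrom, right_lo, right_hi, "five_utr")
        }
      }
    }
  }
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(start = s0 + 1L,
                                                    end = e0))
  mcols(gr)$annot <- an
  gr
}

#' Fractionated genic-annotation scores
#'
#' Collects all (transcript, annotation) hits at each CpG position; if any
#' first-exon hit exists for a CpG, all plain exon hits are removed to avoid
#' redundancy; remaining hit counts are normalised to weights summing to
#' one.  A CpG with no hits gets weight 1 on intergenic.
#'
#' @param chrom,pos Contig names and 0-based CpG positions.
#' @param models Transcript table from [read_gene_models()], or a
#'   pre-built annotation `GRanges` from the internal builder.
#' @return Numeric matrix (CpG x annotation class), rows summing to 1.
#' @export
fractionated_annotation_scores <- function(chrom, pos, models) {
  annot_gr <- if (is(models, "GRanges")) models else
    build_annotation_ranges(models)
  pts <- cpg_granges(chrom, pos)
  hits <- GenomicRanges::findOverlaps(pts, annot_gr)
  acode <- match(mcols(annot_gr)$annot, ANNOTATION_CLASSES)
  n <- length(pts); K <- length(ANNOTATION_CLASSES)
  counts <- matrix(0, n, K, dimnames = list(NULL, ANNOTATION_CLASSES))
  if (length(hits)) {
    tab <- table(factor(queryHits(hits), levels = seq_len(n)),
                 factor(acode[subjectHits(hits)], levels = seq_len(K)))
    counts <- matrix(as.numeric(tab), n, K,
                     dimnames = list(NULL, ANNOTATION_CLASSES))
  }
  fe <- counts[, "first_exon"] > 0
  counts[fe, "exon"] <- 0
  tot <- rowSums(counts)
  counts[tot == 0, "intergenic"] <- 1
  tot[tot == 0] <- 1
  counts / tot
}

#' Annotation enrichment with fractional weights
#'
#' The observed statistic per annotation class is the sum of fractionated
#' weights over the selected CpGs; the null is the same statistic over
#' size-matched random CpG samples from the background, scored and
#' converted to `P = (r + 1) / (n + 1)` as in [monte_carlo_enrichment()].
#'
#' @param selected_weights,background_weights CpG x annotation weight
#'   matrices (rows summing to 1).
#' @param n_sims Number of samplings.
#' @param seed Optional seed.
#' @return Enrichment data.frame (one row per annotation class).
#' @export
annotation_enrichment <- function(selected_weights, background_weights,
                                  n_sims = 1e5, seed = NULL) {
  chk <- function(W) max(abs(rowSums(W) - 1))
  if (chk(selected_weights) > 1e-9 || chk(background_weights) > 1e-9)
    stop_format("annotation weights must sum to 1 per CpG")
  mc_enrichment_weights(selected_weights, background_weights,
                        n_sims = n_sims, seed = seed)
}
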