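# End-to-end orchestration: select -> classify -> subtype -> motifs/ReMap
# -> expression, with deterministic per-stage seeding and a results
# manifest.

#' Pipeline configuration
#'
#' Collects the input paths and tuning constants of a full run.  All
#' referenced files must exist at validation time.
#'
#' @param cpgs,beta,samples,atac,genome,motifs,remap,genes,counts Input
#'   file paths (see the io readers for formats).
#' @param segmentations Named character vector of per-sample segmentation
#'   BED paths; names must be segmentation sample ids of the sample sheet.
#' @param out_dir Output directory.
#' @param thresholds Selection thresholds ([selection_thresholds()]).
#' @param n_sims_chromatin Samplings for chromatin-state and annotation
#'   enrichment (default 1e5).
#' @param n_sims_genes Samplings for gene-category enrichment (default
#'   1e4).
#' @param flank Window flank in bp (default 50).
#' @param de_table Optional path to an externally computed DE table
#'   (TSV: gene_id, log2fc, padj) that replaces the built-in test.
#' @param seed Master seed.
#' @return Validated config list.
#' @export
pipeline_config <- function(cpgs, beta, samples, segmentations, atac,
                            genome, motifs, remap, genes, counts, out_dir,
                            thresholds = selection_thresholds(),
                            n_sims_chromatin = 1e5, n_sims_genes = 1e4,
                            flank = 50, de_table = NULL, seed = 1L) {
  cfg <- list(cpgs = cpgs, beta = beta, samples = samples,
              segmentations = segmentations, atac = atac, genome = genome,
              motifs = motifs, remap = remap, genes = genes,
              counts = counts, out_dir = out_dir, thresholds = thresholds,
              n_sims_chromatin = n_sims_chromatin,
              n_sims_genes = n_sims_genes, flank = flank,
              de_table = de_table, seed = as.integer(seed))
  stopifnot(n_sims_chromatin >= 100, n_sims_genes >= 100)
  files <- c(cpgs, beta, samples, segmentations, atac, genome, motifs,
             remap, genes, counts, de_table)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop_format("input file(s) not found: %s",
                paste(missing, collapse = ", "))
  if (is.null(names(segmentations)) || any(!nzchar(names(segmentations))))
    stop_format("segmentations must be named by sample id")
  cfg
}

#' Pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML config path.
#' @param out_dir Optional override of the output directory.
#' @return Validated config list.
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  segs <- unlist(y$segmentations)
  thr <- if (!is.null(y$thresholds))
    do.call(selection_thresholds, y$thresholds) else selection_thresholds()
  pipeline_config(
    cpgs = resolve(y$cpgs), beta = resolve(y$beta),
    samples = resolve(y$samples),
    segmentations = stats::setNames(resolve(segs), names(segs)),
    atac = resolve(y$atac), genome = resolve(y$genome),
    motifs = resolve(y$motifs), remap = resolve(y$remap),
    genes = resolve(y$genes), counts = resolve(y$counts),
    out_dir = out_dir %||% y$out_dir %||% file.path(base, "results"),
    n_sims_chromatin = y$n_sims_chromatin %||% 1e5,
    n_sims_genes = y$n_sims_genes %||% 1e4,
    flank = y$flank %||% 50,
    de_table = if (!is.null(y$de_table)) resolve(y$de_table) else NULL,
    seed = y$seed %||% 1L)
}

#' Convenience: pipeline config over a generated dataset directory
#'
#' @param dataset Result of [generate_dataset()] (or its `paths` element).
#' @param out_dir Output directory.
#' @param ... Further arguments to [pipeline_config()].
#' @return Validated config list.
#' @export
pipeline_config_from_dataset <- function(dataset, out_dir, ...) {
  p <- dataset$paths %||% dataset
  pipeline_config(cpgs = p$cpgs, beta = p$beta, samples = p$samples,
                  segmentations = p$segmentations, atac = p$atac,
                  genome = p$genome, motifs = p$motifs, remap = p$remap,
                  genes = p$genes, counts = p$counts, out_dir = out_dir,
                  ...)
}

# final category order used for motif / ReMap / gene-enrichment loops
PIPELINE_CATEGORIES <- c("Active", "Inactive", "ActiveAccessible",
                         "ActiveInaccessible", "NBC-hom", "NBC-het")

#' Run the full demethylation-imprint pipeline
#'
#' Stage order: CpG selection (tumor/normal thresholds + drift filter);
#' hierarchical chromatin classification in cMCL and NBC-B with
#' accessibility split and chromatin-state / genic-annotation enrichment;
#' NBC-het/NBC-hom clustering of the inactive CpGs with the best-split
#' threshold; motif and TF-peak enrichment per category against the shared
#' methylated-NBC background; closest-gene assignment, expression
#' categories and probe-density-corrected gene-category enrichment.  Each
#' stage's table is written before the next starts; a checksum manifest is
#' written last.  Identical config + seed give byte-identical outputs.
#'
#' @param config From [pipeline_config()].
#' @return Invisible manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  written <- character(0)
  emit <- function(df, name) {
    f <- file.path(out, name)
    data.table::fwrite(df, f, sep = "\t", quote = FALSE, na = "NA")
    written <<- c(written, f)
    f
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop_format("stage %s failed: %s", name, conditionMessage(e))
    })
  }

  ## ---- load ------------------------------------------------------------
  sheet <- read_sample_sheet(config$samples)
  cpgs <- read_cpg_table(config$cpgs)
  beta <- read_beta_matrix(config$beta, sheet)
  beta <- beta[cpgs$probe_id, , drop = FALSE]

  ## ---- stage 1: selection ----------------------------------------------
  mi_log("pipeline", "stage 1: selection")
  sel_tab <- stage("selection", {
    pm <- population_mean_beta(beta, sheet)
    select_cmcl_specific(pm, config$thresholds)
  })
  emit(sel_tab, "selected.tsv")
  selected <- sel_tab$selected
  sel_ids <- sel_tab$probe_id[selected]
  nbc_mean <- sel_tab$NBC

  ## ---- stage 2: chromatin classification -------------------------------
  mi_log("pipeline", "stage 2: chromatin classification")
  cls <- stage("classification", {
    seg_sheet <- sheet[sheet$assay == "segmentation", , drop = FALSE]
    missing <- setdiff(seg_sheet$sample, names(config$segmentations))
    if (length(missing))
      stop_format("no segmentation file for sample(s): %s",
                  paste(missing, collapse = ", "))
    state_mats <- list()
    for (p in c("cMCL", "NBC-B")) {
      ids <- seg_sheet$sample[seg_sheet$population == p]
      if (!length(ids)) stop_format("no segmentation samples for %s", p)
      m <- vapply(ids, function(sid) {
        seg <- read_segmentation(config$segmentations[[sid]])
        state_at_position(seg, cpgs$chrom, cpgs$pos, cpgs$probe_id)
      }, character(nrow(cpgs)))
      state_mats[[p]] <- m
    }
    hier_cmcl <- classify_state_matrix(state_mats[["cMCL"]])
    hier_nbc <- classify_state_matrix(state_mats[["NBC-B"]])
    peaks <- read_bed_peaks(config$atac)
    acc <- split_by_accessibility(cpgs$chrom, cpgs$pos,
                                  merge_active(hier_cmcl), peaks)
    data.frame(probe_id = cpgs$probe_id, chrom = cpgs$chrom,
               pos = cpgs$pos, selected = selected,
               hier_cMCL = hier_cmcl, merged_cMCL = merge_active(hier_cmcl),
               hier_NBCB = hier_nbc, merged_NBCB = merge_active(hier_nbc),
               accessible = acc$accessible, refined_cMCL = acc$refined)
  })

  chrom_enr <- stage("chromatin_enrichment", monte_carlo_enrichment(
    cls$hier_cMCL[selected], cls$hier_cMCL,
    n_sims = config$n_sims_chromatin, seed = child_seed(seed, 21)))
  emit(chrom_enr, "chromatin_enrichment.tsv")

  annot <- stage("annotation", {
    models <- read_gene_models(config$genes)
    W <- fractionated_annotation_scores(cpgs$chrom, cpgs$pos, models)
    list(models = models, W = W)
  })
  annot_enr <- stage("annotation_enrichment", annotation_enrichment(
    annot$W[selected, , drop = FALSE], annot$W,
    n_sims = config$n_sims_chromatin, seed = child_seed(seed, 22)))
  emit(annot_enr, "annotation_enrichment.tsv")
  emit(proximity_fraction(cls$chrom[selected], cls$pos[selected],
                          cls$merged_cMCL[selected]),
       "proximity.tsv")

  ## ---- stage 3: NBC-het / NBC-hom subtypes -----------------------------
  mi_log("pipeline", "stage 3: NBC subtypes")
  sub <- stage("subtypes", {
    inact <- selected & cls$merged_cMCL == "Inactive"
    nbc_cols <- sheet$sample[sheet$assay == "methylation" &
                               sheet$population %in% c("NBC-B", "NBC-T")]
    if (sum(inact) < 2)
      stop_format("fewer than 2 inactive selected CpGs")
    assign <- cluster_inactive_cpgs(beta[cls$probe_id[inact], nbc_cols,
                                         drop = FALSE])
    thr <- best_split_threshold(assign$mean_nbc_beta, assign$label)
    list(assign = assign, threshold = thr)
  })
  emit(sub$assign, "subtypes.tsv")
  meta <- attr(sub$assign, "metadata")
  jsonlite::write_json(
    list(threshold = sub$threshold$threshold,
         n_errors = sub$threshold$n_errors,
         linkage = meta$method, metric = meta$metric,
         mean_silhouette = meta$mean_silhouette),
    file.path(out, "subtypes_meta.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(out, "subtypes_meta.json"))

  # final per-CpG category of the selection
  final_cat <- cls$refined_cMCL
  final_cat[match(sub$assign$probe_id, cls$probe_id)] <- sub$assign$label
  cls$final_category <- ifelse(selected, final_cat, NA_character_)
  emit(cls, "classified.tsv")

  cat_members <- function(cat) {
    ids <- switch(cat,
      "Active" = cls$probe_id[selected & cls$merged_cMCL == "Active"],
      "Inactive" = cls$probe_id[selected & cls$merged_cMCL == "Inactive"],
      "ActiveAccessible" = cls$probe_id[selected &
                                          cls$refined_cMCL == "ActiveAccessible"],
      "ActiveInaccessible" = cls$probe_id[selected &
                                            cls$refined_cMCL == "ActiveInaccessible"],
      "NBC-hom" = sub$assign$probe_id[sub$assign$label == "NBC-hom"],
      "NBC-het" = sub$assign$probe_id[sub$assign$label == "NBC-het"])
    ids
  }

  ## ---- stage 4: motif / TF-peak enrichment -----------------------------
  mi_log("pipeline", "stage 4: motif and TF-peak enrichment")
  bg_ids <- cls$probe_id[!selected & !is.na(nbc_mean) & nbc_mean > 0.75]
  bg_df <- cls[match(bg_ids, cls$probe_id), c("probe_id", "chrom", "pos")]
  motif_results <- stage("motifs", {
    genome <- read_genome(config$genome)
    pfms <- read_jaspar_pfms(config$motifs)
    fits <- motif_background_fits(bg_df, pfms, genome, config$flank)
    res <- list()
    for (cat in PIPELINE_CATEGORIES) {
      ids <- cat_members(cat)
      if (length(ids) < 2) {
        mi_log("pipeline", sprintf("category %s has < 2 CpGs; skipped", cat))
        next
      }
      tg <- cls[match(ids, cls$probe_id), c("probe_id", "chrom", "pos")]
      res[[cat]] <- run_motif_enrichment(tg, bg_df, pfms, genome,
                                         flank = config$flank,
                                         bg_fits = fits)
      emit(res[[cat]], sprintf("motifs_%s.tsv", gsub("-", "_", cat)))
    }
    res
  })
  remap_results <- stage("remap", {
    tf_peaks <- read_bed_peaks(config$remap, name_col = TRUE)
    res <- list()
    for (cat in names(motif_results)) {
      sel_tfs <- motif_results[[cat]]$tf[motif_results[[cat]]$selected]
      if (!length(sel_tfs)) next
      ids <- cat_members(cat)
      tg <- cls[match(ids, cls$probe_id), c("probe_id", "chrom", "pos")]
      res[[cat]] <- remap_binding_enrichment(tg, bg_df, tf_peaks,
                                             flank = config$flank,
                                             tfs = unique(sel_tfs))
      emit(res[[cat]], sprintf("remap_%s.tsv", gsub("-", "_", cat)))
    }
    res
  })

  ## ---- stage 5: expression ---------------------------------------------
  mi_log("pipeline", "stage 5: expression")
  expr <- stage("expression", {
    genes <- gene_level_models(annot$models)
    assign <- assign_closest_gene(cpgs$chrom, cpgs$pos, genes,
                                  cpgs$probe_id)
    counts <- read_counts_matrix(config$counts)
    exlen <- gene_exonic_lengths(annot$models)[rownames(counts)]
    fp <- fpkm(counts, exlen)
    flags <- expression_flags(fp, sheet)
    if (!is.null(config$de_table)) {
      de <- as.data.frame(data.table::fread(config$de_table))
      de <- de[match(rownames(counts), de$gene_id), ]
    } else {
      rna <- sheet[sheet$assay == "rnaseq", , drop = FALSE]
      groups <- rna$population[match(colnames(counts), rna$sample)]
      de <- differential_expression(counts, groups)
    }
    category <- classify_expression_category(
      flags$expressed[, "cMCL"], flags$expressed[, "NBC-B"],
      de$log2fc, de$padj)
    rec <- data.frame(gene_id = rownames(counts),
                      mean_log_cMCL = flags$mean_log[, "cMCL"],
                      mean_log_NBCB = flags$mean_log[, "NBC-B"],
                      expressed_cMCL = flags$expressed[, "cMCL"],
                      expressed_NBCB = flags$expressed[, "NBC-B"],
                      log2fc = de$log2fc, padj = de$padj,
                      category = category, row.names = NULL)
    list(assign = assign, record = rec)
  })
  emit(expr$assign, "gene_assignment.tsv")
  emit(expr$record, "expression.tsv")

  gene_cats <- stats::setNames(expr$record$category, expr$record$gene_id)
  gene_enr <- stage("gene_enrichment", {
    res <- list()
    k <- 0L
    for (cat in PIPELINE_CATEGORIES) {
      k <- k + 1L
      ids <- cat_members(cat)
      if (!length(ids)) next
      res[[cat]] <- gene_category_enrichment(
        ids, bg_ids, expr$assign, gene_cats,
        n_sims = config$n_sims_genes, seed = child_seed(seed, 40 + k))
      emit(res[[cat]], sprintf("gene_enrichment_%s.tsv",
                               gsub("-", "_", cat)))
    }
    res
  })

  ## ---- manifest ---------------------------------------------------------
  manifest <- list(
    seed = seed,
    n_cpgs = nrow(cpgs),
    n_selected = length(sel_ids),
    category_sizes = lapply(stats::setNames(PIPELINE_CATEGORIES,
                                            PIPELINE_CATEGORIES),
                            function(cat) length(cat_members(cat))),
    best_split_threshold = sub$threshold$threshold,
    outputs = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  mi_log("pipeline", sprintf("done: %d selected of %d CpGs",
                             length(sel_ids), nrow(cpgs)))
  invisible(manifest)
}
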