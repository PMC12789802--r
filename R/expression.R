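# Stage 5: CpG-to-gene assignment, expression categories in cMCL vs NBC-B,
# and probe-density-corrected gene-category enrichment.

#' Assign each CpG to its closest protein-coding gene
#'
#' Intragenic CpGs (position within a gene span) are assigned to the host
#' gene; with several overlapping hosts, the one whose TSS is nearest wins,
#' remaining ties broken by lexicographic gene id.  Intergenic CpGs are
#' assigned to the gene with the nearest TSS on the same contig
#' (strand-aware TSS; ties lexicographic).  CpGs on contigs without genes
#' are left unassigned (logged).
#'
#' @param chrom,pos Contig names and 0-based CpG positions.
#' @param genes Gene-level table from [gene_level_models()].
#' @param probe_id Optional probe ids.
#' @return data.frame: probe_id, gene_id, relation
#'   (intragenic-host / intergenic-nearest-TSS / unassigned),
#'   distance (bp to the TSS, 0 if inside).
#' @export
assign_closest_gene <- function(chrom, pos, genes, probe_id = NULL) {
  n <- length(pos)
  if (is.null(probe_id)) probe_id <- as.character(seq_len(n))
  gene_id <- rep(NA_character_, n)
  relation <- rep("unassigned", n)
  distance <- rep(NA_real_, n)

  pts <- cpg_granges(chrom, pos)
  spans <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(start = genes$start + 1L,
                                                   end = genes$end))
  # suppress the benign seqlevel-mismatch warning for gene-free contigs
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pts, spans))
  if (length(hits)) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    d_tss <- abs(pos[qh] - genes$tss[sh])
    ord <- order(qh, d_tss, genes$gene_id[sh])
    first <- !duplicated(qh[ord])
    pick_q <- qh[ord][first]; pick_s <- sh[ord][first]
    gene_id[pick_q] <- genes$gene_id[pick_s]
    relation[pick_q] <- "intragenic-host"
    distance[pick_q] <- 0
  }

  todo <- which(relation == "unassigned")
  for (ct in unique(chrom[todo])) {
    gi <- which(genes$chrom == ct)
    ci <- todo[chrom[todo] == ct]
    if (!length(gi)) {
      mi_log("expression", sprintf(
        "%d CpG(s) on contig %s with no genes left unassigned",
        length(ci), ct))
      next
    }
    # nearest TSS with lexicographic tie-break on gene id
    ord <- order(genes$tss[gi], genes$gene_id[gi])
    tss <- genes$tss[gi][ord]; ids <- genes$gene_id[gi][ord]
    iv <- findInterval(pos[ci], tss)
    for (j in seq_along(ci)) {
      cand <- unique(pmin(pmax(c(iv[j], iv[j] + 1L), 1L), length(tss)))
      dd <- abs(pos[ci[j]] - tss[cand])
      # all candidates at the minimal distance, then lexicographic min id
      at_min <- cand[dd == min(dd)]
      best <- at_min[order(ids[at_min])][1]
      gene_id[ci[j]] <- ids[best]
      relation[ci[j]] <- "intergenic-nearest-TSS"
      distance[ci[j]] <- abs(pos[ci[j]] - tss[best])
    }
  }
  data.frame(probe_id = probe_id, gene_id = gene_id, relation = relation,
             distance = distance, row.names = NULL)
}

#' FPKM from a count matrix
#'
#' `FPKM[g, s] = count[g, s] / (length_g / 1000) / (colsum_s / 1e6)`, with
#' library sizes taken as the column totals of the count matrix.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param gene_lengths_bp Positive gene lengths in bp (named or in row
#'   order).
#' @return FPKM matrix.
#' @export
fpkm <- function(counts, gene_lengths_bp) {
  stopifnot(all(counts >= 0), all(gene_lengths_bp > 0),
            length(gene_lengths_bp) == nrow(counts))
  lib <- colSums(counts)
  if (any(lib == 0)) stop_format("zero library size")
  t(t(counts / (gene_lengths_bp / 1000)) / (lib / 1e6))
}

#' Per-population mean log-expression and expressed flags
#'
#' For each gene and population, the mean over samples of
#' `log10(FPKM + 0.01)`; a gene is expressed in a population iff that mean
#' is strictly above 0 (FPKM > 1).
#'
#' @param fpkm_mat FPKM matrix (gene x sample).
#' @param sample_sheet Sample sheet; rnaseq-assay rows are used.
#' @return list with `mean_log` (gene x population) and `expressed`
#'   (logical, same shape).
#' @export
expression_flags <- function(fpkm_mat, sample_sheet) {
  rna <- sample_sheet[sample_sheet$assay == "rnaseq", , drop = FALSE]
  missing_cols <- setdiff(rna$sample, colnames(fpkm_mat))
  if (length(missing_cols))
    stop_format("rnaseq sample(s) absent from FPKM matrix: %s",
                paste(missing_cols, collapse = ", "))
  pops <- split(rna$sample, rna$population)
  lg <- log10(fpkm_mat + 0.01)
  mean_log <- vapply(pops, function(cols)
    rowMeans(lg[, cols, drop = FALSE]), numeric(nrow(fpkm_mat)))
  list(mean_log = mean_log, expressed = mean_log > 0)
}

#' Simplified negative-binomial Wald differential expression
#'
#' Median-of-ratios size factors (geometric-mean reference over genes with
#' all-positive counts); per-gene dispersion by method of moments on
#' normalized counts (floored); log2 fold change of normalized group means
#' with a 0.5 pseudocount; Wald z from the negative-binomial variance of
#' the group means; BH adjustment.  A user-supplied table of externally
#' computed statistics can be used instead (see `run_pipeline`'s
#' `de_table`).
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per column.
#' @param test,ref Labels of the test (numerator) and reference group
#'   (default cMCL vs NBC-B).
#' @param dispersion_floor Minimum dispersion (default 1e-8).
#' @return data.frame: gene_id, base_mean, log2fc, se, p, padj.
#' @export
differential_expression <- function(counts, groups, test = "cMCL",
                                    ref = "NBC-B",
                                    dispersion_floor = 1e-8) {
  stopifnot(ncol(counts) == length(groups))
  i1 <- which(groups == test); i2 <- which(groups == ref)
  if (length(i1) < 2 || length(i2) < 2)
    stop_format("need >= 2 samples per group (%s: %d, %s: %d)",
                test, length(i1), ref, length(i2))
  sub <- counts[, c(i1, i2), drop = FALSE]
  if (any(colSums(sub) == 0)) stop_format("a sample has zero total counts")
  sf <- size_factors_mor(sub)
  norm <- sweep(sub, 2, sf, "/")
  g1 <- seq_along(i1); g2 <- length(i1) + seq_along(i2)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  # method-of-moments dispersion, pooled over groups where defined
  a1 <- ifelse(mu1 > 0, (v1 - mu1) / mu1^2, NA_real_)
  a2 <- ifelse(mu2 > 0, (v2 - mu2) / mu2^2, NA_real_)
  alpha <- rowMeans(cbind(a1, a2), na.rm = TRUE)
  alpha[is.nan(alpha) | is.na(alpha)] <- dispersion_floor
  alpha <- pmax(alpha, dispersion_floor)
  lfc <- log2((mu1 + 0.5) / (mu2 + 0.5))
  var_mean1 <- (mu1 + alpha * mu1^2) / length(g1)
  var_mean2 <- (mu2 + alpha * mu2^2) / length(g2)
  se <- sqrt(var_mean1 / (mu1 + 0.5)^2 + var_mean2 / (mu2 + 0.5)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(counts), base_mean = (mu1 + mu2) / 2,
             log2fc = lfc, se = se, p = p,
             padj = stats::p.adjust(p, method = "BH"), row.names = NULL)
}

# Median-of-ratios size factors (geometric-mean reference).
size_factors_mor <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop_format("no gene with all-positive counts")
  log_geo <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - log_geo)))
}

#' Six-category expression classification
#'
#' The rules are applied strictly in order, first match wins:
#' (i) not expressed -- not expressed in either cMCL or NBC-B;
#' (ii) stable expression -- `abs(log2 FC) < 1` or adjusted p >= 0.1;
#' (iii) lost expression -- expressed in NBC-B but not in cMCL;
#' (iv) downregulated -- `log2 FC <= -1` and adjusted p < 0.1;
#' (v) de novo expression -- expressed in cMCL but not in NBC-B;
#' (vi) upregulated -- `log2 FC > 1` and adjusted p < 0.1.
#' With `strict_order = TRUE`, rules (iii)/(v) are evaluated before (ii)
#' (sensitivity analysis for the literal precedence).
#'
#' @param expressed_cmcl,expressed_nbc Logical vectors.
#' @param log2fc,padj DE statistics (may be NA only for genes caught by
#'   rule (i)).
#' @param strict_order Reorder (iii)/(v) before (ii)? Default FALSE
#'   (literal order).
#' @return Character vector of categories.
#' @export
classify_expression_category <- function(expressed_cmcl, expressed_nbc,
                                         log2fc, padj,
                                         strict_order = FALSE) {
  n <- length(expressed_cmcl)
  stopifnot(length(expressed_nbc) == n, length(log2fc) == n,
            length(padj) == n)
  out <- rep(NA_character_, n)
  rule1 <- !expressed_cmcl & !expressed_nbc
  out[rule1] <- "not expressed"
  todo <- which(is.na(out))
  if (any(is.na(log2fc[todo]) | is.na(padj[todo])))
    stop_format("gene past rule (i) with missing DE statistics")
  apply_rules <- function(idx, rules) {
    for (r in rules) {
      hit <- idx[r$test(idx)]
      out[hit] <<- r$label
      idx <- setdiff(idx, hit)
    }
    idx
  }
  r_stable <- list(label = "stable expression",
                   test = function(i) abs(log2fc[i]) < 1 | padj[i] >= 0.1)
  r_lost <- list(label = "lost expression",
                 test = function(i) expressed_nbc[i] & !expressed_cmcl[i])
  r_down <- list(label = "downregulated",
                 test = function(i) log2fc[i] <= -1 & padj[i] < 0.1)
  r_denovo <- list(label = "de novo expression",
                   test = function(i) expressed_cmcl[i] & !expressed_nbc[i])
  r_up <- list(label = "upregulated",
               test = function(i) log2fc[i] > 1 & padj[i] < 0.1)
  rules <- if (strict_order)
    list(r_lost, r_denovo, r_stable, r_down, r_up)
  else
    list(r_stable, r_lost, r_down, r_denovo, r_up)
  left <- apply_rules(todo, rules)
  # the only reachable leftover is log2fc exactly 1 with padj < 0.1;
  # treated as stable so the categories partition the gene set
  out[left] <- "stable expression"
  out
}

#' Gene-category enrichment with probe-density correction
#'
#' The observed statistic per category is the fraction of the *unique* set
#' of closest genes of the selection falling in that category.  The null
#' repeats the unique-gene mapping inside each size-matched random CpG
#' sample from the background -- this corrects for CpG probe density around
#' genes.  Scoring and `P = (r + 1)/(n + 1)` as in
#' [monte_carlo_enrichment()]; genes absent from the expression table are
#' not considered.
#'
#' @param selected_ids,background_ids CpG probe ids.
#' @param assignments data.frame from [assign_closest_gene()] covering all
#'   ids.
#' @param gene_categories Named character vector: category per gene (genes
#'   in the expression data only).
#' @param n_sims Number of samplings (default 10000).
#' @param seed Optional seed.
#' @return Enrichment data.frame with observed/expected fractions, fold,
#'   `p_enrich`, `p_deplete`, plus `n_genes_observed`.
#' @export
gene_category_enrichment <- function(selected_ids, background_ids,
                                     assignments, gene_categories,
                                     n_sims = 10000, seed = NULL) {
  if (!length(selected_ids) || !length(background_ids))
    stop_format("empty selection or background")
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  amap <- assignments$gene_id
  names(amap) <- assignments$probe_id
  miss <- setdiff(c(selected_ids, background_ids), assignments$probe_id)
  if (length(miss))
    mi_log("expression", sprintf("%d CpG(s) without gene assignment ignored",
                                 length(miss)))
  cats <- EXPRESSION_CATEGORIES
  genes <- names(gene_categories)
  cat_code <- match(gene_categories, cats)

  frac_of <- function(ids) {
    g <- unique(amap[ids])
    g <- g[!is.na(g)]
    code <- cat_code[match(g, genes)]
    code <- code[!is.na(code)]  # genes not in the expression data dropped
    if (!length(code)) return(list(frac = rep(0, length(cats)), n = 0L))
    list(frac = tabulate(code, nbins = length(cats)) / length(code),
         n = length(code))
  }
  obs <- frac_of(selected_ids)
  n <- length(selected_ids); N <- length(background_ids)
  bg_gene <- amap[background_ids]          # may contain NA
  K <- length(cats)
  r_en <- numeric(K); r_de <- numeric(K); tot <- numeric(K)
  bg_code_by_gene <- cat_code[match(unique(c(bg_gene, names(cat_code))),
                                    genes)]
  for (s in seq_len(n_sims)) {
    g <- unique(bg_gene[sample.int(N, n)])
    g <- g[!is.na(g)]
    code <- cat_code[match(g, genes)]
    code <- code[!is.na(code)]
    frac <- if (length(code))
      tabulate(code, nbins = K) / length(code) else rep(0, K)
    r_en <- r_en + (frac >= obs$frac)
    r_de <- r_de + (frac <= obs$frac)
    tot <- tot + frac
  }
  expected <- tot / n_sims
  data.frame(class = cats,
             observed = obs$frac,
             expected = expected,
             fold = ifelse(expected > 0, obs$frac / expected,
                           ifelse(obs$frac > 0, Inf, NA_real_)),
             r_enrich = r_en, r_deplete = r_de, n_sims = n_sims,
             p_enrich = (r_en + 1) / (n_sims + 1),
             p_deplete = (r_de + 1) / (n_sims + 1),
             n_genes_observed = obs$n,
             row.names = NULL)
}
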