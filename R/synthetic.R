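# Synthetic dataset with planted ground truth for every pipeline stage.
#
# Geometry: CpG probes sit on a jittered 500-bp grid (so +/-50 bp windows
# and accessibility peaks never collide between probes); genes occupy fixed
# 2-kb spans inside 5-kb blocks.  Planted demethylation classes, chromatin
# states, motif insertions, TF peaks and expression programs are all
# internally consistent and recorded in a truth table.

# Genome-wide chromatin-state frequencies used for background bins/CpGs
# (heterochromatin/low-signal dominated, as in lymphocyte segmentations).
STATE_BG_PROBS <- c(E1 = 0.02, E2 = 0.015, E3 = 0.02, E4 = 0.01,
                    E5 = 0.03, E6 = 0.015, E7 = 0.015, E8 = 0.07,
                    E9 = 0.04, E10 = 0.08, E11 = 0.60, E12 = 0.085)

INACTIVE_TIER <- c("E8", "E10", "E11", "E12")

#' Simulation configuration
#'
#' Defaults mirror the real study's scale where it is stated (sample
#' counts per population; ~300 inactive CpGs split ~3:1 het:hom) and a
#' 2 x 5 Mb toy genome with 20 000 CpGs.  The CpG count is tied to the
#' genome (one probe per 500 bp), which guarantees non-overlapping probe
#' windows.
#'
#' @param contigs Named vector of contig lengths (bp, multiples of 5000).
#' @param n_cpgs Number of CpG probes; must equal `sum(contigs) / 500`.
#' @param meth_samples Named vector of methylation sample counts per
#'   population.
#' @param seg_samples Segmentation sample counts (cMCL and NBC-B).
#' @param rna_samples RNA-seq sample counts per population.
#' @param n_active,n_accessible,n_nbc_hom,n_nbc_het,n_drift Planted class
#'   sizes (`n_accessible` is a subset of `n_active`).
#' @param n_bg_methylated Number of constitutively methylated background
#'   CpGs (the motif/gene background, with the drift CpGs).
#' @param n_genes Number of protein-coding genes (per contig at most
#'   `length / 5000`).
#' @param beta_precision Beta-distribution concentration for methylation
#'   noise.
#' @param het_fraction NBC subpopulation fraction f for NBC-het CpGs.
#' @param het_low,het_high Subpopulation / majority NBC beta means mixed
#'   by f.
#' @param state_keep_prob Per-sample probability that a bin keeps its
#'   planted state.
#' @param nb_dispersion Negative-binomial dispersion of RNA counts.
#' @param motif_length,n_decoy_motifs,plant_rate_inactive,plant_rate_active
#'   Motif-planting geometry.
#' @param consensus_planting Insert the consensus (default) or sample each
#'   base from the PFM.
#' @param seed Master seed.
#' @return Validated config list.
#' @export
simulation_config <- function(contigs = c(chr1 = 5e6, chr2 = 5e6),
                              n_cpgs = 20000,
                              meth_samples = c(HPC = 6, EarlyB = 16,
                                               `NBC-B` = 10, `NBC-T` = 5,
                                               GCBC = 9, MBC = 10,
                                               `PB/PC` = 11, cMCL = 62,
                                               nnMCL = 20),
                              seg_samples = c(cMCL = 2, `NBC-B` = 3),
                              rna_samples = c(`NBC-B` = 3, `NBC-T` = 3,
                                              GCBC = 3, MBC = 3,
                                              `PB/PC` = 3, cMCL = 2),
                              n_active = 600, n_accessible = 150,
                              n_nbc_hom = 80, n_nbc_het = 230,
                              n_drift = 400, n_bg_methylated = 6000,
                              n_genes = 2000,
                              beta_precision = 100,
                              het_fraction = 0.15,
                              het_low = 0.10, het_high = 0.93,
                              state_keep_prob = 0.9,
                              nb_dispersion = 0.05,
                              motif_length = 10, n_decoy_motifs = 37,
                              plant_rate_inactive = 0.6,
                              plant_rate_active = 0.3,
                              consensus_planting = TRUE,
                              seed = 1L) {
  stopifnot(all(contigs %% 5000 == 0), all(contigs > 0))
  if (sum(contigs) != 500 * n_cpgs)
    stop_format("n_cpgs must equal sum(contigs)/500 (one probe per 500 bp)")
  stopifnot(het_fraction > 0, het_fraction < 1,
            beta_precision > 0, nb_dispersion > 0,
            state_keep_prob > 0, state_keep_prob <= 1,
            n_accessible <= n_active, motif_length >= 6)
  n_planted_genes <- n_active + n_nbc_hom + n_nbc_het
  if (n_planted_genes > n_genes)
    stop_format("planted classes need %d genes but n_genes = %d",
                n_planted_genes, n_genes)
  genes_per_contig <- round(n_genes * contigs / sum(contigs))
  if (any(genes_per_contig > contigs / 5000))
    stop_format("too many genes for the genome (max one per 5-kb block)")
  if (n_active + n_nbc_hom + n_nbc_het + n_drift + n_bg_methylated > n_cpgs)
    stop_format("planted class counts exceed n_cpgs")
  list(contigs = contigs, n_cpgs = n_cpgs, meth_samples = meth_samples,
       seg_samples = seg_samples, rna_samples = rna_samples,
       n_active = n_active, n_accessible = n_accessible,
       n_nbc_hom = n_nbc_hom, n_nbc_het = n_nbc_het, n_drift = n_drift,
       n_bg_methylated = n_bg_methylated, n_genes = n_genes,
       genes_per_contig = genes_per_contig,
       beta_precision = beta_precision, het_fraction = het_fraction,
       het_low = het_low, het_high = het_high,
       state_keep_prob = state_keep_prob, nb_dispersion = nb_dispersion,
       motif_length = motif_length, n_decoy_motifs = n_decoy_motifs,
       plant_rate_inactive = plant_rate_inactive,
       plant_rate_active = plant_rate_active,
       consensus_planting = consensus_planting, seed = as.integer(seed))
}

#' Draw beta-distributed methylation values
#'
#' Values are drawn from Beta(mean * precision, (1 - mean) * precision).
#' A mean of exactly 0 or 1 is clamped to `[1e-3, 1 - 1e-3]` with a
#' warning.
#'
#' @param mean Target mean(s) in `(0, 1)`.
#' @param precision Concentration (> 0).
#' @param n Number of draws (recycled against `mean`).
#' @return Numeric vector of draws in `(0, 1)`.
#' @export
simulate_beta <- function(mean, precision, n = length(mean)) {
  stopifnot(precision > 0)
  if (any(mean <= 0 | mean >= 1)) {
    warning("beta mean clamped away from {0, 1}")
    mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  }
  stats::rbeta(n, mean * precision, (1 - mean) * precision)
}

# Per-class, per-population beta means.  het NBC mean is the f-mixture of a
# demethylated subpopulation and the methylated majority.
class_beta_means <- function(config) {
  het_nbc <- config$het_fraction * config$het_low +
    (1 - config$het_fraction) * config$het_high
  pops <- names(config$meth_samples)
  classes <- c("active", "active_accessible", "nbc_hom", "nbc_het",
               "drift", "bg_methylated", "bg_unmethylated")
  m <- matrix(NA_real_, length(classes), length(pops),
              dimnames = list(classes, pops))
  m["active", ] <- c(0.92, 0.92, 0.92, 0.92, 0.92, 0.92, 0.92, 0.08, 0.60)
  m["active_accessible", ] <- m["active", ]
  m["nbc_hom", ] <- m["active", ]
  m["nbc_het", ] <- m["active", ]
  m["nbc_het", c("NBC-B", "NBC-T")] <- het_nbc
  m["drift", ] <- m["active", ]
  m["drift", c("GCBC", "MBC", "PB/PC")] <- 0.30
  m["drift", "nnMCL"] <- 0.30
  m["bg_methylated", ] <- 0.90
  m["bg_unmethylated", ] <- 0.10
  m
}

# sample a replacement state different from `base`, from candidate set
resample_states <- function(base, candidates, probs = NULL) {
  out <- sample(candidates, length(base), replace = TRUE, prob = probs)
  bad <- which(out == base)
  while (length(bad)) {
    out[bad] <- sample(candidates, length(bad), replace = TRUE, prob = probs)
    bad <- bad[out[bad] == base[bad]]
  }
  out
}

# noisy per-sample copy of a baseline state vector: keep with probability
# keep_prob; otherwise draw a different state -- from the other inactive
# states when the baseline is inactive-tier (replicate disagreement at
# silent loci stays within the inactive flavors), from all other states
# otherwise.
noisy_states <- function(baseline, keep_prob) {
  out <- baseline
  flip <- which(stats::runif(length(baseline)) >= keep_prob)
  if (!length(flip)) return(out)
  inact <- flip[baseline[flip] %in% INACTIVE_TIER]
  act <- setdiff(flip, inact)
  if (length(inact))
    out[inact] <- resample_states(baseline[inact], INACTIVE_TIER)
  if (length(act))
    out[act] <- resample_states(baseline[act], CHROM_STATES)
  out
}

random_consensus <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

consensus_pfm <- function(consensus, id, tf, hit = 85, miss = 5) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(miss, 4, length(b), dimnames = list(c("A", "C", "G", "T"),
                                                  NULL))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- hit
  attr(m, "id") <- id
  attr(m, "tf") <- tf
  m
}

#' Generate the complete synthetic dataset
#'
#' Writes, under `out_dir`: the probe table, beta matrix, sample sheet,
#' per-sample chromatin segmentations, cMCL accessibility peaks, genome
#' FASTA with planted motif instances, JASPAR motif file, ReMap-style TF
#' peak BED, gene models, RNA-seq counts, and a `truth/` directory with
#' the planted classes plus a checksum manifest.  Byte-identical outputs
#' for identical config + seed.
#'
#' @param config From [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default `config$seed`).
#' @return Invisible list with file `paths` and in-memory `truth` tables.
#' @export
generate_dataset <- function(config, out_dir, seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  contigs <- config$contigs

  ## --- layout: probes on a jittered 500-bp grid -------------------------
  set.seed(child_seed(seed, 1))
  slots_per_contig <- contigs / 500
  chrom <- rep(names(contigs), slots_per_contig)
  slot_in_contig <- unlist(lapply(slots_per_contig, seq_len), use.names = FALSE)
  jitter <- sample.int(200, config$n_cpgs, replace = TRUE) - 1L
  pos <- (slot_in_contig - 1L) * 500L + 150L + jitter
  probe_id <- sprintf("cg%08d", seq_len(config$n_cpgs))

  ## --- genes: evenly spread over 5-kb blocks ----------------------------
  gpc <- config$genes_per_contig
  gene_rows <- list()
  gidx <- 0L
  planted_slot <- integer(config$n_genes)   # global CpG index inside gene
  reserved <- integer(0)
  offset_slots <- cumsum(c(0, slots_per_contig))[seq_along(contigs)]
  names(offset_slots) <- names(contigs)
  for (ci in seq_along(contigs)) {
    B <- contigs[ci] / 5000
    G <- gpc[ci]
    blocks <- floor((seq_len(G) - 1) * B / G)
    for (b in blocks) {
      gidx <- gidx + 1L
      gstart <- b * 5000L + 1500L
      strand <- if (gidx %% 2 == 0) "-" else "+"
      gene_rows[[gidx]] <- data.frame(
        transcript_id = sprintf("T%04d.1", gidx),
        gene_id = sprintf("G%04d", gidx),
        chrom = names(contigs)[ci], strand = strand,
        start = gstart, end = gstart + 2000L,
        exon_starts = I(list(c(gstart, gstart + 1200L))),
        exon_ends = I(list(c(gstart + 400L, gstart + 2000L))),
        cds_start = gstart + 200L, cds_end = gstart + 1600L, coding = 1L)
      planted_slot[gidx] <- offset_slots[ci] + b * 10L + 5L
      reserved <- c(reserved, offset_slots[ci] + b * 10L + c(4L, 6L, 7L))
    }
  }
  models <- do.call(rbind, gene_rows)
  # a second, shifted transcript for ~10% of genes (multi-transcript CpGs)
  extra <- sort(sample.int(config$n_genes, max(1, config$n_genes %/% 10)))
  extra_rows <- lapply(extra, function(g) {
    r <- models[g, ]
    r$transcript_id <- sprintf("T%04d.2", g)
    gstart <- r$start
    r$exon_starts <- I(list(c(gstart + 100L, gstart + 1100L)))
    r$exon_ends <- I(list(c(gstart + 500L, gstart + 1900L)))
    r$cds_start <- gstart + 300L
    r$cds_end <- gstart + 1500L
    r
  })
  models <- rbind(models, do.call(rbind, extra_rows))

  ## --- planted classes --------------------------------------------------
  set.seed(child_seed(seed, 2))
  n_planted <- config$n_active + config$n_nbc_hom + config$n_nbc_het
  planted_genes <- sample.int(config$n_genes, n_planted)
  active_genes <- planted_genes[seq_len(config$n_active)]
  hom_genes <- planted_genes[config$n_active + seq_len(config$n_nbc_hom)]
  het_genes <- planted_genes[config$n_active + config$n_nbc_hom +
                               seq_len(config$n_nbc_het)]
  class <- rep("bg_unmethylated", config$n_cpgs)
  class[planted_slot[active_genes]] <- "active"
  acc_genes <- sample(active_genes, config$n_accessible)
  class[planted_slot[acc_genes]] <- "active_accessible"
  class[planted_slot[hom_genes]] <- "nbc_hom"
  class[planted_slot[het_genes]] <- "nbc_het"
  taken <- c(planted_slot[planted_genes], reserved)
  free <- setdiff(seq_len(config$n_cpgs), taken)
  pick <- sample(free, config$n_drift + config$n_bg_methylated)
  class[pick[seq_len(config$n_drift)]] <- "drift"
  class[pick[config$n_drift + seq_len(config$n_bg_methylated)]] <-
    "bg_methylated"

  ## --- beta matrix ------------------------------------------------------
  set.seed(child_seed(seed, 3))
  cm <- class_beta_means(config)
  pops <- names(config$meth_samples)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%02d", gsub("[/-]", "", p), seq_len(config$meth_samples[[p]]))),
    use.names = FALSE)
  sample_pop <- rep(pops, config$meth_samples)
  mean_mat <- cm[class, sample_pop, drop = FALSE]
  beta <- matrix(round(simulate_beta(as.vector(mean_mat),
                                     config$beta_precision,
                                     length(mean_mat)), 6),
                 nrow = config$n_cpgs,
                 dimnames = list(probe_id, sample_ids))

  ## --- chromatin states -------------------------------------------------
  set.seed(child_seed(seed, 4))
  planted_state_cmcl <- character(config$n_cpgs)
  is_active <- class %in% c("active", "active_accessible")
  is_inactive <- class %in% c("nbc_hom", "nbc_het", "drift")
  is_bg <- !is_active & !is_inactive
  planted_state_cmcl[is_active] <- sample(c("E2", "E6"), sum(is_active),
                                          replace = TRUE)
  planted_state_cmcl[is_inactive] <- sample(INACTIVE_TIER, sum(is_inactive),
                                            replace = TRUE)
  planted_state_cmcl[is_bg] <- sample(names(STATE_BG_PROBS), sum(is_bg),
                                      replace = TRUE, prob = STATE_BG_PROBS)
  planted_state_nbc <- planted_state_cmcl
  planted_state_nbc[is_active] <- sample(INACTIVE_TIER, sum(is_active),
                                         replace = TRUE)

  seg_paths <- character(0)
  seg_sheet <- list()
  nbins <- contigs / 200
  bin_chrom <- rep(names(contigs), nbins)
  bin_start <- unlist(lapply(nbins, function(n) (seq_len(n) - 1L) * 200L),
                      use.names = FALSE)
  cpg_bin <- offsetted_bin_index(chrom, pos, contigs)
  baseline_for <- function(cpg_states) {
    base <- sample(names(STATE_BG_PROBS), sum(nbins), replace = TRUE,
                   prob = STATE_BG_PROBS)
    base[cpg_bin] <- cpg_states
    base
  }
  base_cmcl <- baseline_for(planted_state_cmcl)
  base_nbc <- baseline_for(planted_state_nbc)
  for (p in names(config$seg_samples)) {
    base <- if (p == "cMCL") base_cmcl else base_nbc
    for (k in seq_len(config$seg_samples[[p]])) {
      sid <- sprintf("%s_seg_%02d", gsub("[/-]", "", p), k)
      st <- noisy_states(base, config$state_keep_prob)
      f <- file.path(out_dir, paste0("seg_", sid, ".bed"))
      data.table::fwrite(data.frame(bin_chrom, bin_start, bin_start + 200L,
                                    st),
                         f, sep = "\t", quote = FALSE, col.names = FALSE)
      seg_paths[sid] <- f
      seg_sheet[[sid]] <- data.frame(sample = sid, population = p,
                                     assay = "segmentation")
    }
  }

  ## --- accessibility peaks ----------------------------------------------
  acc <- class == "active_accessible"
  atac_path <- file.path(out_dir, "atac_cmcl.bed")
  data.table::fwrite(data.frame(chrom[acc], pos[acc] - 50L, pos[acc] + 51L),
                     atac_path, sep = "\t", quote = FALSE,
                     col.names = FALSE)

  ## --- genome + motifs --------------------------------------------------
  set.seed(child_seed(seed, 5))
  L <- config$motif_length
  repeat {
    planted_cons <- vapply(1:3, function(i) random_consensus(L), "")
    d <- c(hamming(planted_cons[1], planted_cons[2]),
           hamming(planted_cons[1], planted_cons[3]),
           hamming(planted_cons[2], planted_cons[3]))
    if (min(d) >= 5) break
  }
  decoy_cons <- vapply(seq_len(config$n_decoy_motifs),
                       function(i) random_consensus(L), "")
  motif_tf <- c("SYNTF_ACT", "SYNTF_HOM", "SYNTF_HET",
                sprintf("SYNTF_D%02d", seq_len(config$n_decoy_motifs)))
  motif_id <- sprintf("SM%04d", seq_along(motif_tf))
  consensi <- c(planted_cons, decoy_cons)
  pfms <- lapply(seq_along(consensi), function(i)
    consensus_pfm(consensi[i], motif_id[i], motif_tf[i]))
  names(pfms) <- motif_id
  motif_path <- file.path(out_dir, "motifs.jaspar")
  write_jaspar_pfms(pfms, motif_path)

  base_chars <- lapply(contigs, function(len)
    sample(c("A", "C", "G", "T"), len, replace = TRUE))
  # plant the CpG dinucleotide at every probe position
  for (ci in names(contigs)) {
    sel <- chrom == ci
    base_chars[[ci]][pos[sel] + 1L] <- "C"
    base_chars[[ci]][pos[sel] + 2L] <- "G"
  }
  plant_class <- c(active = 1L, active_accessible = 1L, nbc_hom = 2L,
                   nbc_het = 3L)
  plant_rate <- c(config$plant_rate_active, config$plant_rate_inactive,
                  config$plant_rate_inactive)
  motif_planted <- rep(NA_character_, config$n_cpgs)
  motif_offset <- rep(NA_integer_, config$n_cpgs)
  plantable <- which(class %in% names(plant_class))
  for (i in plantable) {
    mi <- plant_class[[class[i]]]
    if (stats::runif(1) >= plant_rate[mi]) next
    # offsets keeping the motif inside +/-50 bp and off the CpG itself
    allowed <- c(seq(pos[i] - 50L, pos[i] - L), seq(pos[i] + 2L, pos[i] + 51L - L))
    o <- allowed[sample.int(length(allowed), 1)]
    ins <- if (config$consensus_planting) strsplit(consensi[mi], "")[[1]]
    else vapply(seq_len(L), function(j)
      sample(rownames(pfms[[mi]]), 1, prob = pfms[[mi]][, j]), "")
    base_chars[[chrom[i]]][(o + 1L):(o + L)] <- ins
    motif_planted[i] <- motif_id[mi]
    motif_offset[i] <- o - pos[i]
  }
  genome <- Biostrings::DNAStringSet(vapply(base_chars, paste, "",
                                            collapse = ""))
  names(genome) <- names(contigs)
  genome_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_path)

  ## --- ReMap-style TF peaks ---------------------------------------------
  set.seed(child_seed(seed, 6))
  bg_set <- which(class %in% c("bg_methylated", "drift"))
  peak_rows <- list()
  planted_idx <- which(!is.na(motif_planted))
  if (length(planted_idx))
    peak_rows[["planted"]] <- data.frame(
      chrom = chrom[planted_idx], start = pos[planted_idx] - 40L,
      end = pos[planted_idx] + 41L,
      name = motif_tf[match(motif_planted[planted_idx], motif_id)])
  for (ti in seq_along(motif_tf)) {
    hit <- bg_set[stats::runif(length(bg_set)) < 0.02]
    if (!length(hit)) next
    peak_rows[[motif_tf[ti]]] <- data.frame(
      chrom = chrom[hit], start = pos[hit] - 40L, end = pos[hit] + 41L,
      name = motif_tf[ti])
  }
  remap <- do.call(rbind, peak_rows)
  remap <- remap[order(remap$chrom, remap$start, remap$name), ]
  remap_path <- file.path(out_dir, "remap.bed")
  data.table::fwrite(remap, remap_path, sep = "\t", quote = FALSE,
                     col.names = FALSE)

  ## --- expression programs ----------------------------------------------
  set.seed(child_seed(seed, 7))
  gene_class <- rep(NA_character_, config$n_genes)
  gene_class[active_genes] <- "upregulated"
  gene_class[hom_genes] <- "de novo expression"
  gene_class[het_genes] <- "stable expression"
  bg_rates <- c("stable expression" = 0.70, "not expressed" = 0.15,
                "de novo expression" = 0.03, "lost expression" = 0.04,
                "downregulated" = 0.04, "upregulated" = 0.04)
  unset <- which(is.na(gene_class))
  gene_class[unset] <- sample(names(bg_rates), length(unset),
                              replace = TRUE, prob = bg_rates)
  # target FPKM (ref = normal populations, test = cMCL)
  fpkm_ref <- c("stable expression" = 300, "not expressed" = 0.05,
                "de novo expression" = 0.05, "lost expression" = 300,
                "downregulated" = 300, "upregulated" = 300)
  fpkm_test <- c("stable expression" = 300, "not expressed" = 0.05,
                 "de novo expression" = 600, "lost expression" = 0.05,
                 "downregulated" = 60, "upregulated" = 1200)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  exlen <- gene_exonic_lengths(models)[gene_ids]
  rna_pops <- names(config$rna_samples)
  rna_ids <- unlist(lapply(rna_pops, function(p)
    sprintf("%s_rna_%02d", gsub("[/-]", "", p),
            seq_len(config$rna_samples[[p]]))), use.names = FALSE)
  rna_pop <- rep(rna_pops, config$rna_samples)
  depth <- 0.1   # counts per (FPKM x kb)
  counts <- matrix(0L, config$n_genes, length(rna_ids),
                   dimnames = list(gene_ids, rna_ids))
  for (s in seq_along(rna_ids)) {
    f <- if (rna_pop[s] == "cMCL") fpkm_test[gene_class] else
      fpkm_ref[gene_class]
    mu <- f * (exlen / 1000) * depth
    counts[, s] <- stats::rnbinom(config$n_genes, mu = mu,
                                  size = 1 / config$nb_dispersion)
  }

  ## --- write tables ------------------------------------------------------
  paths <- list(
    cpgs = file.path(out_dir, "cpgs.tsv"),
    beta = file.path(out_dir, "beta.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    segmentations = seg_paths,
    atac = atac_path,
    genome = genome_path,
    motifs = motif_path,
    remap = remap_path,
    genes = file.path(out_dir, "genes.tsv"),
    counts = file.path(out_dir, "counts.tsv"))
  data.table::fwrite(data.frame(probe_id, chrom, pos), paths$cpgs,
                     sep = "\t", quote = FALSE)
  write_beta_matrix(beta, paths$beta)
  sheet <- rbind(
    data.frame(sample = sample_ids, population = sample_pop,
               assay = "methylation"),
    do.call(rbind, seg_sheet),
    data.frame(sample = "cMCL_atac", population = "cMCL",
               assay = "accessibility"),
    data.frame(sample = rna_ids, population = rna_pop, assay = "rnaseq"))
  write_sample_sheet(sheet, paths$samples)
  write_gene_models(models, paths$genes)
  data.table::fwrite(data.frame(gene_id = gene_ids, counts,
                                check.names = FALSE),
                     paths$counts, sep = "\t", quote = FALSE)

  ## --- truth tables + manifest -------------------------------------------
  merged_truth <- ifelse(is_active, "Active",
                         ifelse(is_inactive, "Inactive",
                                merge_active(vapply(planted_state_cmcl,
                                                    classify_population_state,
                                                    ""))))
  cpg_truth <- data.frame(
    probe_id, chrom, pos, class,
    planted_state_cmcl, planted_state_nbc,
    planted_category = merged_truth,
    accessible = acc,
    het_fraction = ifelse(class == "nbc_het", config$het_fraction,
                          NA_real_),
    motif_id = motif_planted, motif_offset = motif_offset)
  gene_truth <- data.frame(
    gene_id = gene_ids, expression_class = gene_class,
    planted_cpg_class = ifelse(gene_ids %in% gene_ids[active_genes],
                               "active",
                        ifelse(gene_ids %in% gene_ids[hom_genes], "nbc_hom",
                        ifelse(gene_ids %in% gene_ids[het_genes], "nbc_het",
                               NA_character_))))
  motif_truth <- data.frame(
    motif_id = motif_id[1:3], tf = motif_tf[1:3],
    target_class = c("active", "nbc_hom", "nbc_het"),
    consensus = planted_cons)
  tpaths <- list(cpg = file.path(out_dir, "truth", "cpg_truth.tsv"),
                 gene = file.path(out_dir, "truth", "gene_truth.tsv"),
                 motif = file.path(out_dir, "truth", "motif_truth.tsv"))
  data.table::fwrite(cpg_truth, tpaths$cpg, sep = "\t", quote = FALSE,
                     na = "NA")
  data.table::fwrite(gene_truth, tpaths$gene, sep = "\t", quote = FALSE,
                     na = "NA")
  data.table::fwrite(motif_truth, tpaths$motif, sep = "\t", quote = FALSE,
                     na = "NA")
  all_files <- c(unlist(paths, use.names = FALSE), unlist(tpaths,
                                                          use.names = FALSE))
  manifest <- list(seed = seed,
                   n_cpgs = config$n_cpgs,
                   checksums = as.list(tools::md5sum(sort(all_files))))
  jsonlite::write_json(manifest, file.path(out_dir, "truth", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth_paths = tpaths,
                 truth = list(cpg = cpg_truth, gene = gene_truth,
                              motif = motif_truth)))
}

# global bin index (over concatenated contigs) of each CpG
offsetted_bin_index <- function(chrom, pos, contigs) {
  nbins <- contigs / 200
  off <- cumsum(c(0, nbins))[seq_along(contigs)]
  names(off) <- names(contigs)
  off[chrom] + pos %/% 200 + 1L
}

#' Exonic (union) gene lengths from transcript models
#' @param models Transcript table from [read_gene_models()].
#' @return Named vector of union-exon lengths in bp per gene.
#' @export
gene_exonic_lengths <- function(models) {
  sp <- split(seq_len(nrow(models)), models$gene_id)
  vapply(sp, function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = unlist(models$exon_starts[idx]) + 1L,
      end = unlist(models$exon_ends[idx])))
    sum(IRanges::width(ir))
  }, numeric(1))
}
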