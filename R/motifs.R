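# Stage 4: PWM motif enrichment against a lognormal tile background, the
# top-motif-percentage statistic, and TF peak-overlap enrichment.

#' Extract fixed-width sequence windows around CpGs
#'
#' Each CpG is extended by `flank` bp on each side, giving plus-strand
#' sequences of length `2 * flank + 1`.  CpGs whose window would run past a
#' contig end are dropped (logged).
#'
#' @param chrom,pos Contig names and 0-based CpG positions.
#' @param genome `DNAStringSet` genome.
#' @param flank Flank size in bp (default 50).
#' @param probe_id Optional probe ids carried through as names.
#' @return `DNAStringSet` of uppercase windows; attribute `kept` holds the
#'   indices of the retained CpGs.
#' @export
extract_windows <- function(chrom, pos, genome, flank = 50,
                            probe_id = NULL) {
  stopifnot(length(chrom) == length(pos))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stop_format("CpG on unknown contig: %s", unknown[1])
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  keep <- which(pos - flank >= 0 & pos + flank <= lens - 1L)
  if (length(keep) < length(pos))
    mi_log("motifs", sprintf("%d window(s) dropped at contig edges",
                             length(pos) - length(keep)))
  if (!length(keep)) stop_format("no windows left after edge filtering")
  parts <- lapply(split(keep, chrom[keep]), function(idx) {
    ct <- chrom[idx[1]]
    s <- Biostrings::DNAStringSet(
      Biostrings::Views(genome[[ct]],
                        start = pos[idx] + 1L - flank,
                        end = pos[idx] + 1L + flank))
    names(s) <- if (!is.null(probe_id)) probe_id[idx] else as.character(idx)
    s
  })
  out <- do.call(c, unname(parts))
  # restore input order
  ord <- if (!is.null(probe_id)) match(probe_id[keep], names(out)) else
    match(as.character(keep), names(out))
  out <- out[ord]
  out <- Biostrings::DNAStringSet(toupper(as.character(out)))
  attr(out, "kept") <- keep
  out
}

# Integer code matrix (A=1, C=2, G=3, T=4, other NA) for equal-width
# sequences; the workhorse representation of the vectorised scorer.
seq_int_matrix <- function(seqs) {
  cm <- as.matrix(seqs)
  m <- match(cm, c("A", "C", "G", "T"))
  dim(m) <- dim(cm)
  m
}

#' Background base frequencies of a sequence set
#' @param seqs `DNAStringSet`.
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @export
background_base_freqs <- function(seqs) {
  f <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  f / sum(f)
}

#' Convert a PFM to a log2-odds PWM
#'
#' Column probabilities use one pseudocount distributed by the background
#' frequencies: `p[b, j] = (count[b, j] + q[b]) / (N_j + 1)`; PWM entries
#' are `log2(p / q)`.
#'
#' @param pfm 4 x L non-negative count matrix (rows A, C, G, T).
#' @param background_base_freqs Positive frequencies summing to 1.
#' @return 4 x L PWM with attributes `id`/`tf` copied from the PFM.
#' @export
pfm_to_pwm <- function(pfm, background_base_freqs) {
  stopifnot(nrow(pfm) == 4, all(pfm >= 0))
  q <- background_base_freqs
  stopifnot(length(q) == 4, all(q > 0), abs(sum(q) - 1) < 1e-6)
  Nj <- colSums(pfm)
  if (any(Nj <= 0)) stop_format("zero-total PFM column")
  p <- sweep(pfm, 2, Nj + 1, "/") + q %o% (1 / (Nj + 1))
  pwm <- log2(p / q)
  dimnames(pwm) <- list(c("A", "C", "G", "T"), NULL)
  attr(pwm, "id") <- attr(pfm, "id")
  attr(pwm, "tf") <- attr(pfm, "tf")
  pwm
}

reverse_complement_pwm <- function(pwm) pwm[4:1, ncol(pwm):1, drop = FALSE]

# Window log2 scores for all sequences at once: out[i, w] = sum_j
# pwm[S[i, w + j - 1], j].  NA bases propagate to NA window scores.
pwm_window_scores <- function(S, pwm) {
  L <- ncol(pwm); W <- ncol(S) - L + 1L
  if (W < 1) stop_format("sequence shorter than motif")
  out <- matrix(0, nrow(S), W)
  for (j in seq_len(L)) {
    Vj <- matrix(pwm[(j - 1L) * 4L + S], nrow(S))
    out <- out + Vj[, j:(j + W - 1L), drop = FALSE]
  }
  out
}

# Mean odds (2^log2score) over all windows on both strands, for a code
# matrix of equal-length sequences.  Windows containing non-ACGT bases are
# skipped; all-skipped sequences give NA.
affinity_scores_matrix <- function(S, pwm) {
  fwd <- 2^pwm_window_scores(S, pwm)
  rev <- 2^pwm_window_scores(S, reverse_complement_pwm(pwm))
  rowMeans(cbind(fwd, rev), na.rm = TRUE)
}

#' Mean-odds affinity score of a sequence under a PWM
#'
#' The score is the mean over all motif-length windows, on both strands, of
#' `2^(sum of PWM entries)`.  Windows containing non-ACGT bases are
#' skipped; if every window is skipped the score is undefined (error).
#'
#' @param sequence A single sequence (character or `DNAString`).
#' @param pwm 4 x L PWM from [pfm_to_pwm()].
#' @return The affinity score (positive scalar).
#' @export
affinity_score <- function(sequence, pwm) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < ncol(pwm)) stop_format("sequence shorter than motif")
  S <- matrix(match(strsplit(s, "")[[1]], c("A", "C", "G", "T")), nrow = 1)
  sc <- affinity_scores_matrix(S, pwm)
  if (is.nan(sc)) stop_format("all windows contain non-ACGT bases")
  sc
}

#' Fit the lognormal background of a motif on background tiles
#'
#' The per-CpG background windows serve directly as the ~100-bp tiles; the
#' null parameters are the mean and standard deviation of the natural log
#' of the affinity score across tiles, with the standard deviation floored.
#'
#' @param background_seqs `DNAStringSet` of background windows, or the
#'   integer code matrix from the internal converter.
#' @param pwm 4 x L PWM.
#' @param sigma_floor Lower bound for sigma (default 1e-6).
#' @param min_tiles Minimum number of scoreable tiles (default 30).
#' @return list with `mu` and `sigma`.
#' @export
fit_lognormal_background <- function(background_seqs, pwm,
                                     sigma_floor = 1e-6, min_tiles = 30) {
  S <- if (is.matrix(background_seqs)) background_seqs else
    seq_int_matrix(background_seqs)
  sc <- affinity_scores_matrix(S, pwm)
  sc <- sc[!is.na(sc) & !is.nan(sc)]
  if (length(sc) < min_tiles)
    stop_format("only %d scoreable background tiles (< %d)", length(sc),
                min_tiles)
  lsc <- log(sc)
  sigma <- stats::sd(lsc)
  if (!is.finite(sigma) || sigma < sigma_floor) {
    warning("degenerate background; sigma floored")
    sigma <- sigma_floor
  }
  list(mu = mean(lsc), sigma = sigma)
}

#' Group p-value of a target set under the lognormal background
#'
#' The statistic is the mean affinity score of the targets.  The null of
#' the mean of N iid LogNormal(mu, sigma^2) scores is approximated by a
#' lognormal via Fenton-Wilkinson moment matching:
#' `sigma_N^2 = log(1 + (exp(sigma^2) - 1)/N)`,
#' `mu_N = mu + sigma^2/2 - sigma_N^2/2`; the p-value is the upper tail at
#' the statistic.  With N = 1 this reduces to the plain lognormal tail.
#'
#' @param target_scores Positive affinity scores of the target windows.
#' @param mu,sigma Background parameters from
#'   [fit_lognormal_background()].
#' @return Upper-tail p-value.
#' @export
group_pvalue <- function(target_scores, mu, sigma) {
  target_scores <- target_scores[!is.na(target_scores)]
  if (!length(target_scores)) stop_format("no target scores")
  if (any(target_scores <= 0)) stop_format("non-positive affinity score")
  N <- length(target_scores)
  s2N <- log1p((exp(sigma^2) - 1) / N)
  muN <- mu + sigma^2 / 2 - s2N / 2
  stats::plnorm(mean(target_scores), meanlog = muN, sdlog = sqrt(s2N),
                lower.tail = FALSE)
}

#' Top-motif percentage per motif
#'
#' For each sequence, motifs are ranked by their per-sequence lognormal
#' p-value (ascending, ties sharing the minimal rank); a motif counts as
#' "top" for that sequence when its rank is within the top 5% of motifs
#' (cutoff `ceiling(0.05 * M)`).  The statistic is the percentage of
#' sequences in which the motif is top.
#'
#' @param pval_matrix Motif x sequence matrix of per-sequence p-values.
#' @param top_frac Fraction defining "top" (default 0.05).
#' @return Named numeric vector of percentages (0-100).
#' @export
top_motif_percentage <- function(pval_matrix, top_frac = 0.05) {
  M <- nrow(pval_matrix)
  if (M < 2) stop_format("need at least 2 motifs to rank")
  cutoff <- ceiling(top_frac * M)
  top <- apply(pval_matrix, 2, function(p)
    rank(p, ties.method = "min") <= cutoff)
  pct <- 100 * rowMeans(top)
  names(pct) <- rownames(pval_matrix)
  pct
}

#' Motif enrichment of target CpG windows against a CpG background
#'
#' Extracts +/-`flank` bp windows for both sets, computes background base
#' frequencies from the background windows, converts each PFM to a PWM,
#' fits the per-motif lognormal null on the background tiles, and reports
#' per motif the group p-value and the top-motif percentage.  A motif is
#' selected when the top percentage is at least `top_pct_min` and the group
#' p-value is below `p_max`.  CpGs present in both sets are removed from
#' the background with a warning.
#'
#' @param targets,background data.frames with columns probe_id, chrom, pos.
#' @param pfms Named list of PFMs ([read_jaspar_pfms()]).
#' @param genome `DNAStringSet` genome.
#' @param flank Window flank (default 50).
#' @param top_pct_min,p_max Selection rule constants (defaults 10 and
#'   0.05).
#' @param bg_fits Optional precomputed list of per-motif background fits
#'   (with matching `pwms` and `bg_freqs` attributes) to reuse across
#'   categories.
#' @return data.frame ranked by p: motif_id, tf, p, top_pct, selected.
#' @export
run_motif_enrichment <- function(targets, background, pfms, genome,
                                 flank = 50, top_pct_min = 10,
                                 p_max = 0.05, bg_fits = NULL) {
  overlap <- intersect(targets$probe_id, background$probe_id)
  if (length(overlap)) {
    warning(sprintf("%d CpG(s) in both target and background; removed from background",
                    length(overlap)))
    background <- background[!background$probe_id %in% overlap, ,
                             drop = FALSE]
  }
  if (is.null(bg_fits))
    bg_fits <- motif_background_fits(background, pfms, genome, flank)
  pwms <- attr(bg_fits, "pwms")
  tw <- extract_windows(targets$chrom, targets$pos, genome, flank,
                        targets$probe_id)
  St <- seq_int_matrix(tw)
  M <- length(pwms)
  pvals <- numeric(M)
  pseq <- matrix(NA_real_, M, nrow(St),
                 dimnames = list(names(pwms), NULL))
  for (m in seq_len(M)) {
    fit <- bg_fits[[m]]
    sc <- affinity_scores_matrix(St, pwms[[m]])
    pvals[m] <- group_pvalue(sc, fit$mu, fit$sigma)
    pseq[m, ] <- stats::plnorm(sc, fit$mu, fit$sigma, lower.tail = FALSE)
  }
  top_pct <- top_motif_percentage(pseq)
  out <- data.frame(
    motif_id = names(pwms),
    tf = vapply(pwms, function(w) attr(w, "tf") %||% NA_character_, ""),
    p = pvals,
    top_pct = unname(top_pct),
    selected = unname(top_pct >= top_pct_min & pvals < p_max),
    row.names = NULL)
  out[order(out$p), ]
}

#' Precompute per-motif background fits
#'
#' Computes background windows, base frequencies, PWMs and lognormal null
#' parameters once, for reuse across target categories sharing one
#' background.
#'
#' @inheritParams run_motif_enrichment
#' @return list of per-motif fits with attributes `pwms` and `bg_freqs`.
#' @export
motif_background_fits <- function(background, pfms, genome, flank = 50) {
  bw <- extract_windows(background$chrom, background$pos, genome, flank,
                        background$probe_id)
  freqs <- background_base_freqs(bw)
  pwms <- lapply(pfms, pfm_to_pwm, background_base_freqs = freqs)
  Sb <- seq_int_matrix(bw)
  fits <- lapply(pwms, function(w) fit_lognormal_background(Sb, w))
  attr(fits, "pwms") <- pwms
  attr(fits, "bg_freqs") <- freqs
  fits
}

#' TF binding-site overlap enrichment (ReMap-style peaks)
#'
#' For each TF, builds the 2x2 table of target/background CpGs whose
#' +/-`flank` bp window intersects at least one peak of that TF, and tests
#' it with Fisher's exact test, BH-corrected across TFs.  TFs with fewer
#' than `min_bg_bound` bound background CpGs are flagged; TFs requested via
#' `tfs` but absent from the peak file are reported as not assessable.
#'
#' @param targets,background data.frames with columns probe_id, chrom, pos.
#' @param tf_peaks `GRanges` with a `name` column carrying the TF.
#' @param flank Window flank in bp (default 50).
#' @param tfs Optional TF names to assess (default: all in the peak file).
#' @param min_bg_bound Background-support flag threshold (default 5).
#' @return data.frame: tf, counts, odds_ratio, p, padj, low_background,
#'   assessable.
#' @export
remap_binding_enrichment <- function(targets, background, tf_peaks,
                                     flank = 50, tfs = NULL,
                                     min_bg_bound = 5) {
  if (is.null(mcols(tf_peaks)$name))
    stop_format("tf_peaks must carry TF names in the 'name' column")
  peak_tfs <- unique(mcols(tf_peaks)$name)
  if (is.null(tfs)) tfs <- peak_tfs
  win <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$pos + 1L - flank,
                               end = df$pos + 1L + flank))
  tg <- win(targets); bg <- win(background)
  n_t <- length(tg); n_b <- length(bg)
  rows <- lapply(tfs, function(tf) {
    if (!tf %in% peak_tfs)
      return(data.frame(tf = tf, n_target_bound = NA_integer_,
                        n_target = n_t, n_bg_bound = NA_integer_,
                        n_bg = n_b, odds_ratio = NA_real_, p = NA_real_,
                        low_background = NA, assessable = FALSE))
    pk <- tf_peaks[mcols(tf_peaks)$name == tf]
    tb <- sum(GenomicRanges::countOverlaps(tg, pk) > 0)
    bb <- sum(GenomicRanges::countOverlaps(bg, pk) > 0)
    if (tb == 0 && bb == 0)
      return(data.frame(tf = tf, n_target_bound = 0L, n_target = n_t,
                        n_bg_bound = 0L, n_bg = n_b,
                        odds_ratio = NA_real_, p = NA_real_,
                        low_background = TRUE, assessable = FALSE))
    ft <- fisher_exact_2x2(tb, n_t - tb, bb, n_b - bb)
    data.frame(tf = tf, n_target_bound = tb, n_target = n_t,
               n_bg_bound = bb, n_bg = n_b,
               odds_ratio = ft$odds_ratio, p = ft$p_value,
               low_background = bb < min_bg_bound, assessable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  ok <- out$assessable
  if (any(ok)) out$padj[ok] <- benjamini_hochberg(out$p[ok])
  out[order(out$p), ]
}
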