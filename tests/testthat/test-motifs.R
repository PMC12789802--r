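test_that("window extraction gives plus-strand sequences of length 2f+1", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100),
                                                    collapse = "")))
  w <- extract_windows("chr1", 200, genome, flank = 50)
  expect_equal(Biostrings::width(w), 101)
  # plus-strand, position 200 (0-based) is an A in the ACGT repeat
  expect_equal(substr(as.character(w[[1]]), 51, 51), "A")
  # window running off the contig start is dropped
  expect_message(w2 <- extract_windows(c("chr1", "chr1"), c(10, 200),
                                       genome, flank = 50), "dropped")
  expect_length(w2, 1)
  expect_equal(attr(w2, "kept"), 2L)
  expect_error(extract_windows("chrZ", 100, genome), "unknown contig")
})

test_that("PFM to PWM uses the background-distributed pseudocount", {
  pfm <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm, uniform_freqs)
  expect_equal(max(abs(pwm)), 0)
  pfm2 <- matrix(c(10, 0, 0, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2 <- pfm_to_pwm(pfm2, uniform_freqs)
  expect_equal(unname(pwm2["A", 1]), log2((10.25 / 11) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm2["A", 1]), 1.898, tolerance = 1e-3)
  # doubling counts moves entries toward the maximum-likelihood log odds
  pwm4 <- pfm_to_pwm(pfm2 * 2, uniform_freqs)
  expect_gt(pwm4["A", 1], pwm2["A", 1])
  expect_lt(pwm4["A", 1], log2(1 / 0.25))
  expect_error(pfm_to_pwm(matrix(0, 4, 2,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)),
                          uniform_freqs), "zero-total")
})

test_that("affinity score follows the two-strand mean-odds definition", {
  pfm <- matrix(c(8, 1, 1, 1,  1, 8, 1, 1,  1, 1, 8, 1), 4, 3,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm, uniform_freqs)
  # sequence length == motif length: one window per strand
  s_fwd <- sum(pwm[cbind(match(c("A", "C", "G"), rownames(pwm)), 1:3)])
  rcpwm <- pwm[4:1, 3:1]
  s_rev <- sum(rcpwm[cbind(match(c("A", "C", "G"), rownames(pwm)), 1:3)])
  expect_equal(affinity_score("ACG", pwm), (2^s_fwd + 2^s_rev) / 2)
  # reverse-palindromic motif scores both strands equally
  pal <- matrix(c(9, 1, 1, 1,  1, 9, 1, 1,  1, 1, 9, 1,  1, 1, 1, 9),
                4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  ppwm <- pfm_to_pwm(pal, uniform_freqs)  # consensus ACGT, its own rev-comp
  S <- methimprint:::seq_int_matrix(random_windows(20, 30, seed = 4))
  fwd <- 2^methimprint:::pwm_window_scores(S, ppwm)
  rev <- 2^methimprint:::pwm_window_scores(
    S, methimprint:::reverse_complement_pwm(ppwm))
  expect_equal(fwd, rev)
  # changing one base to the column's best base strictly increases the score
  expect_gt(affinity_score("ACG", pwm), affinity_score("TCG", pwm))
  expect_error(affinity_score("AC", pwm), "shorter")
  expect_error(affinity_score("NNN", pwm), "non-ACGT")
})

test_that("lognormal background fit is order-invariant with floored sigma", {
  pfm <- methimprint:::consensus_pfm("ACGTAC", "m", "tf", hit = 40,
                                     miss = 20)
  pwm <- pfm_to_pwm(pfm, uniform_freqs)
  w <- random_windows(200, seed = 8)
  f1 <- fit_lognormal_background(w, pwm)
  f2 <- fit_lognormal_background(rev(w), pwm)
  expect_equal(f1, f2)
  # identical tiles degenerate to the sigma floor
  same <- Biostrings::DNAStringSet(rep(as.character(w[1]), 40))
  expect_warning(f3 <- fit_lognormal_background(same, pwm), "floored")
  expect_equal(f3$sigma, 1e-6)
  expect_error(fit_lognormal_background(w[1:10], pwm), "< 30")
})

test_that("group p-value reduces, is monotone, and centres near 0.5", {
  mu <- -2; sigma <- 0.5
  # N = 1 reduces to the plain lognormal tail
  expect_equal(group_pvalue(0.2, mu, sigma),
               plnorm(0.2, mu, sigma, lower.tail = FALSE))
  # strictly decreasing in the statistic
  p <- vapply(c(0.1, 0.15, 0.25), function(s)
    group_pvalue(rep(s, 20), mu, sigma), numeric(1))
  expect_true(all(diff(p) < 0))
  # Monte-Carlo: statistic at the null mean gives p -> 0.5 at large N
  set.seed(31)
  N <- 400
  m0 <- exp(mu + sigma^2 / 2)
  emp <- mean(replicate(4000, mean(rlnorm(N, mu, sigma))) >= m0)
  expect_equal(group_pvalue(rep(m0, N), mu, sigma), emp, tolerance = 0.05)
  expect_error(group_pvalue(c(1, -1), mu, sigma), "non-positive")
})

test_that("top-motif percentage uses the ceiling cutoff and min-rank ties", {
  # M = 40 motifs -> cutoff rank 2
  set.seed(32)
  pm <- matrix(runif(40 * 3), 40, 3,
               dimnames = list(sprintf("m%02d", 1:40), NULL))
  pm[1, 1:2] <- 0   # motif 1 ranked 1st in sequences 1 and 2
  pct <- top_motif_percentage(pm)
  expect_equal(unname(pct["m01"]), 100 * 2 / 3, tolerance = 1e-9)
  # all motifs tied on a sequence share rank 1 <= cutoff
  pm2 <- matrix(0.5, 10, 1, dimnames = list(sprintf("m%d", 1:10), NULL))
  expect_true(all(top_motif_percentage(pm2) == 100))
  expect_error(top_motif_percentage(pm2[1, , drop = FALSE]), "at least 2")
})

test_that("end-to-end motif enrichment detects a planted consensus only", {
  set.seed(33)
  genome_len <- 60000L
  gseq <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  n_cpg <- 260
  pos <- seq(150L, by = 220L, length.out = n_cpg)
  planted_cons <- "TTGACGTCAA"
  target_idx <- 1:60
  planted <- target_idx[1:24]  # 40% of targets carry the consensus
  for (i in planted) {
    o <- pos[i] + 5L
    gseq[(o + 1L):(o + 10L)] <- strsplit(planted_cons, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(gseq, collapse = "")))
  cp <- data.frame(probe_id = sprintf("cg%03d", seq_len(n_cpg)),
                   chrom = "chr1", pos = pos)
  pfms <- c(list(methimprint:::consensus_pfm(planted_cons, "P1", "TFP")),
            lapply(1:19, function(i) methimprint:::consensus_pfm(
              paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                    collapse = ""), sprintf("D%02d", i),
              sprintf("TFD%02d", i))))
  names(pfms) <- vapply(pfms, attr, "", "id")
  res <- run_motif_enrichment(cp[target_idx, ], cp[-target_idx, ], pfms,
                              genome)
  expect_true(res$selected[res$motif_id == "P1"])
  expect_gte(res$top_pct[res$motif_id == "P1"], 10)
  expect_lt(res$p[res$motif_id == "P1"], 0.05)
  # overlap between target and background is removed with a warning
  expect_warning(run_motif_enrichment(cp[1:40, ], cp[1:200, ], pfms[1:3],
                                      genome),
                 "removed from background")
})

test_that("ReMap overlap enrichment reduces to Fisher and flags edge cases", {
  set.seed(34)
  n_t <- 100; n_b <- 900
  cp <- data.frame(probe_id = sprintf("cg%04d", seq_len(n_t + n_b)),
                   chrom = "chr1",
                   pos = seq(200L, by = 300L, length.out = n_t + n_b))
  tg <- cp[1:n_t, ]; bg <- cp[-(1:n_t), ]
  bound_t <- tg$pos[1:10]; bound_b <- bg$pos[1:4]
  pk <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = c(bound_t, bound_b),
                                                width = 1))
  S4Vectors::mcols(pk)$name <- "TF1"
  r <- remap_binding_enrichment(tg, bg, pk)
  ora <- fisher_exact_2x2(10, 90, 4, 896)
  expect_equal(r$odds_ratio[r$tf == "TF1"], ora$odds_ratio)
  expect_equal(r$p[r$tf == "TF1"], ora$p_value)
  expect_true(r$low_background[r$tf == "TF1"])  # only 4 bound background
  # peaks covering nothing -> not assessable
  far <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start = 9e6, width = 10))
  S4Vectors::mcols(far)$name <- "TF2"
  r2 <- remap_binding_enrichment(tg, bg, far)
  expect_false(r2$assessable[r2$tf == "TF2"])
  # requested TF absent from the peak file
  r3 <- remap_binding_enrichment(tg, bg, pk, tfs = c("TF1", "TFX"))
  expect_false(r3$assessable[r3$tf == "TFX"])
})

test_that("planted TF peaks are recovered in the pipeline's own categories", {
  run <- default_run()
  ds <- default_dataset()
  f <- file.path(tempdir(), "mi_default_run", "remap_NBC_hom.tsv")
  expect_true(file.exists(f))
  r <- read_tsv(f)
  hom_tf <- ds$truth$motif$tf[ds$truth$motif$target_class == "nbc_hom"]
  expect_true(hom_tf %in% r$tf)
  expect_lt(r$padj[r$tf == hom_tf], 0.05)
  expect_gt(r$odds_ratio[r$tf == hom_tf], 1)
})
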