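test_that("state lookup respects half-open bins and reports gaps", {
  d <- withr::local_tempdir()
  f <- file.path(d, "seg.bed")
  writeLines(c("chr1\t200\t400\tE5", "chr1\t400\t600\tE1"), f)
  seg <- read_segmentation(f)
  expect_equal(state_at_position(seg, "chr1", 200), "E5")
  expect_equal(state_at_position(seg, "chr1", 399), "E5")
  expect_equal(state_at_position(seg, "chr1", 400), "E1")
  expect_error(state_at_position(seg, "chr1", 700, "cgX"), "cgX")
})

test_that("hierarchy prioritises active annotations as specified", {
  expect_equal(classify_population_state(c("E1", "E11")), "ActivePromoter")
  expect_equal(classify_population_state(c("E7", "E2")),
               "ActiveTranscription")
  expect_equal(classify_population_state(c("E8", "E10", "E11", "E12")),
               "Inactive")
  expect_equal(classify_population_state(c("E5", "E12")), "Primed")
  expect_equal(classify_population_state("E9"), "Other")
  expect_error(classify_population_state(c("E1", "E13")), "E13")
  expect_error(classify_population_state(character(0)), "empty")
})

test_that("merge and accessibility split behave on categories and flags", {
  expect_equal(merge_active(c("ActiveEnhancer", "Primed", "Inactive",
                              "ActivePromoter")),
               c("Active", "Primed", "Inactive", "Active"))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 101, end = 200))
  r <- split_by_accessibility(c("chr1", "chr1", "chr1"),
                              c(150, 200, 150),
                              c("Active", "Active", "Inactive"), peaks)
  expect_equal(r$accessible, c(TRUE, FALSE, TRUE))  # 200 is outside [100,200)
  expect_equal(r$refined, c("ActiveAccessible", "ActiveInaccessible",
                            "Inactive"))  # inactive keeps category
})

test_that("fractionated scores follow hit counting and first-exon removal", {
  base <- data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    start = 10000L, end = 12000L,
    exon_starts = I(list(c(10000L, 11000L))),
    exon_ends = I(list(c(10400L, 12000L))),
    cds_start = 10100L, cds_end = 11800L, coding = 1L)
  # single intron hit
  w <- fractionated_annotation_scores("chr1", 10500, base)
  expect_equal(unname(w[1, "intron"]), 1)
  # first exon of t1 overlapping a plain exon of a second transcript
  t2 <- base
  t2$transcript_id <- "t2"
  t2$exon_starts <- I(list(c(9000L, 10000L)))
  t2$exon_ends <- I(list(c(9500L, 10400L)))
  t2$start <- 9000L
  t2$cds_start <- 9100L; t2$cds_end <- 10300L
  w <- fractionated_annotation_scores("chr1", 10200, rbind(base, t2))
  expect_equal(unname(w[1, "first_exon"]), 1)
  expect_equal(unname(w[1, "exon"]), 0)
  # promoter of one gene + intron of another -> 0.5 / 0.5
  t3 <- base
  t3$transcript_id <- "t3"; t3$gene_id <- "g2"
  t3$start <- 9000L; t3$end <- 10800L
  t3$exon_starts <- I(list(c(9000L, 10700L)))
  t3$exon_ends <- I(list(c(9200L, 10800L)))
  t3$cds_start <- 9050L; t3$cds_end <- 10750L
  w <- fractionated_annotation_scores("chr1", 9500,
                                      rbind(base, t3))  # t1 promoter region
  expect_equal(unname(w[1, "promoter"]), 0.5)
  expect_equal(unname(w[1, "intron"]), 0.5)
  # no hit anywhere -> intergenic
  w <- fractionated_annotation_scores("chr1", 500000, base)
  expect_equal(unname(w[1, "intergenic"]), 1)
})

test_that("annotation weights always sum to one on random models", {
  models <- random_gene_models(seed = 5)
  set.seed(6)
  pos <- sample.int(1e6, 3000)
  chrom <- sample(c("chr1", "chr2"), 3000, replace = TRUE)
  W <- fractionated_annotation_scores(chrom, pos, models)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  expect_true(all(W >= 0))
})

test_that("weighted enrichment reduces to the count test on 0/1 weights", {
  set.seed(9)
  lab <- sample(c("intron", "exon", "promoter"), 300, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  W <- outer(lab, c("intron", "exon", "promoter"), "==") * 1
  colnames(W) <- c("intron", "exon", "promoter")
  sel <- sort(sample.int(300, 40))
  rc <- monte_carlo_enrichment(lab[sel], lab, n_sims = 500, seed = 123)
  rw <- annotation_enrichment(W[sel, ], W, n_sims = 500, seed = 123)
  rw <- rw[match(rc$class, rw$class), ]
  expect_equal(rw$observed, rc$observed)
  expect_equal(rw$p_enrich, rc$p_enrich)
  expect_equal(rw$p_deplete, rc$p_deplete)

  # selection == background -> fold 1, p 1
  r <- annotation_enrichment(W, W, n_sims = 100, seed = 1)
  expect_true(all(r$fold == 1))
  expect_true(all(r$p_enrich == 1))
})

test_that("computed cMCL categories recover the planted ones", {
  run <- default_run()
  ds <- default_dataset()
  cls <- read_tsv(file.path(tempdir(), "mi_default_run", "classified.tsv"))
  truth <- ds$truth$cpg
  planted <- truth$class %in% c("active", "active_accessible", "nbc_hom",
                                "nbc_het")
  idx <- match(truth$probe_id[planted], cls$probe_id)
  agree <- mean(cls$merged_cMCL[idx] == truth$planted_category[planted])
  expect_gte(agree, 0.99)
})
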