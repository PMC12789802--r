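toy_genes <- function() {
  data.frame(gene_id = c("gMinus", "gPlus"), chrom = "chr1",
             strand = c("-", "+"), start = c(300L, 1300L),
             end = c(800L, 2300L), tss = c(799L, 1300L))
}

test_that("closest-gene assignment is host-first then strand-aware TSS", {
  g <- toy_genes()
  r <- assign_closest_gene("chr1", 500, g)
  expect_equal(r$gene_id, "gMinus")
  expect_equal(r$relation, "intragenic-host")
  expect_equal(r$distance, 0)
  # intergenic CpG at 1000: gMinus TSS 799 (d 201) beats gPlus TSS 1300
  r <- assign_closest_gene("chr1", 1000, g)
  expect_equal(r$gene_id, "gMinus")
  expect_equal(r$relation, "intergenic-nearest-TSS")
  expect_equal(r$distance, 201)
  # contig without genes is left unassigned
  expect_message(r <- assign_closest_gene("chr9", 100, g), "no genes")
  expect_equal(r$relation, "unassigned")
})

test_that("assignment agrees with a brute-force scan on random layouts", {
  models <- random_gene_models(seed = 41)
  genes <- gene_level_models(models)
  set.seed(42)
  pos <- sample.int(1e6, 500)
  chrom <- sample(c("chr1", "chr2"), 500, replace = TRUE)
  r <- assign_closest_gene(chrom, pos, genes)
  for (i in sample.int(500, 60)) {
    gi <- genes[genes$chrom == chrom[i], ]
    if (!nrow(gi)) next
    inside <- gi[pos[i] >= gi$start & pos[i] < gi$end, ]
    if (nrow(inside)) {
      d <- abs(pos[i] - inside$tss)
      pick <- inside$gene_id[order(d, inside$gene_id)][1]
      expect_equal(r$gene_id[i], pick)
    } else {
      d <- abs(pos[i] - gi$tss)
      pick <- gi$gene_id[order(d, gi$gene_id)][1]
      expect_equal(r$gene_id[i], pick)
      expect_equal(r$distance[i], min(d))
    }
  }
})

test_that("FPKM follows the unit definition and normalises library size", {
  counts <- matrix(c(100, 0, 999900, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  counts[2, 1] <- 1e6 - 100
  counts[1, 2] <- 0; counts[2, 2] <- 1e6
  f <- fpkm(counts, c(1000, 10000))
  expect_equal(f["g1", "s1"], 100)
  expect_equal(f["g1", "s2"], 0)
  expect_equal(fpkm(counts * 2, c(1000, 10000)), f)
  expect_error(fpkm(matrix(0, 2, 1), c(100, 100)), "zero library")
})

test_that("expressed flags use mean log10(FPKM + 0.01) strictly above 0", {
  fp <- rbind(g1 = c(10, 10), g2 = c(0.5, 0.5), g3 = c(0.99, 0.99))
  colnames(fp) <- c("r1", "r2")
  sheet <- data.frame(sample = c("r1", "r2"), population = "cMCL",
                      assay = "rnaseq")
  fl <- expression_flags(fp, sheet)
  expect_true(fl$expressed["g1", "cMCL"])
  expect_false(fl$expressed["g2", "cMCL"])
  expect_false(fl$expressed["g3", "cMCL"])  # log10(1.00) = 0 is not > 0
  expect_equal(fl$mean_log["g2", "cMCL"], log10(0.51), tolerance = 1e-12)
})

test_that("NB Wald test: size factors, null behaviour, planted recovery", {
  # size factors on (c, 2c) columns are proportional to (1, 2)
  cnt <- matrix(c(10, 50, 200, 20, 100, 400), 3,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  sf <- methimprint:::size_factors_mor(cnt)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # agreement with the reference median-of-ratios implementation
  skip_if_not_installed("DESeq2")
  set.seed(43)
  big <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200)
  dimnames(big) <- list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6))
  expect_equal(unname(methimprint:::size_factors_mor(big)),
               unname(DESeq2::estimateSizeFactorsForMatrix(big)),
               tolerance = 1e-6)

  # identical deep-coverage groups: |log2 FC| < 0.1 for >= 95% of genes
  set.seed(44)
  n_g <- 400
  counts <- matrix(rnbinom(n_g * 10, mu = 2000, size = 1 / 0.001), n_g)
  dimnames(counts) <- list(sprintf("g%03d", 1:n_g), sprintf("s%d", 1:10))
  groups <- rep(c("cMCL", "NBC-B"), each = 5)
  de <- differential_expression(counts, groups)
  expect_gte(mean(abs(de$log2fc) < 0.1), 0.95)

  # 4-fold genes planted among a stable majority recovered near log2 FC = 2
  # (a subset, so median-of-ratios normalization is anchored by the rest)
  planted <- 1:40
  mu <- matrix(200, n_g, 10)
  mu[planted, 1:5] <- 800
  counts2 <- matrix(rnbinom(n_g * 10, mu = mu, size = 1 / 0.05), n_g)
  dimnames(counts2) <- dimnames(counts)
  de2 <- differential_expression(counts2, groups)
  expect_gt(mean(de2$log2fc[planted]), 1.7)
  expect_lt(mean(de2$log2fc[planted]), 2.3)
  expect_gte(mean(de2$padj[planted] < 0.1), 0.95)
  expect_error(differential_expression(counts[, 1:3],
                                       c("cMCL", "cMCL", "NBC-B")),
               ">= 2 samples")
})

test_that("six-category hierarchy is literal, ordered and partitioning", {
  cl <- classify_expression_category(
    expressed_cmcl = c(FALSE, TRUE, TRUE, FALSE),
    expressed_nbc = c(FALSE, TRUE, FALSE, TRUE),
    log2fc = c(NA, 0.5, 2.5, -0.5),
    padj = c(NA, 0.001, 0.01, 0.5))
  expect_equal(cl, c("not expressed", "stable expression",
                     "de novo expression", "stable expression"))
  # the literal order sends non-significant NBC-only genes to stable;
  # strict mode reorders lost/de-novo ahead of stable
  cl2 <- classify_expression_category(FALSE, TRUE, -0.5, 0.5,
                                      strict_order = TRUE)
  expect_equal(cl2, "lost expression")
  # downregulated and upregulated branches
  expect_equal(classify_expression_category(TRUE, TRUE, -2, 0.01),
               "downregulated")
  expect_equal(classify_expression_category(TRUE, TRUE, 2, 0.01),
               "upregulated")
  # partition property on random inputs
  set.seed(45)
  n <- 300
  ec <- sample(c(TRUE, FALSE), n, TRUE)
  en <- sample(c(TRUE, FALSE), n, TRUE)
  fc <- rnorm(n, 0, 2)
  pa <- runif(n)
  cats <- classify_expression_category(ec, en, fc, pa)
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("not expressed", "stable expression",
                              "lost expression", "downregulated",
                              "de novo expression", "upregulated")))
  expect_error(classify_expression_category(TRUE, TRUE, NA, 0.2),
               "missing DE")
})

test_that("gene-category enrichment maps unique genes inside each sample", {
  assignments <- data.frame(probe_id = c("c1", "c2", "c3", "c4"),
                            gene_id = c("g1", "g1", "g2", "g3"),
                            relation = "intragenic-host", distance = 0)
  cats <- c(g1 = "de novo expression", g2 = "stable expression",
            g3 = "stable expression")
  # two selected CpGs mapping to one gene contribute that gene once
  r <- gene_category_enrichment(c("c1", "c2"), c("c1", "c2", "c3", "c4"),
                                assignments, cats, n_sims = 200, seed = 1)
  expect_equal(r$n_genes_observed[1], 1L)
  expect_equal(r$observed[r$class == "de novo expression"], 1)
  # selection == background -> fold 1, p 1 in every category
  r2 <- gene_category_enrichment(c("c1", "c2", "c3", "c4"),
                                 c("c1", "c2", "c3", "c4"),
                                 assignments, cats, n_sims = 100, seed = 2)
  present <- r2$expected > 0
  expect_equal(r2$fold[present], rep(1, sum(present)))
  expect_true(all(r2$p_enrich == 1))

  # one-gene-per-CpG reduction agrees with the hypergeometric oracle
  set.seed(46)
  n_bg <- 600
  ids <- sprintf("p%03d", seq_len(n_bg))
  glab <- sprintf("G%03d", seq_len(n_bg))
  lab <- sample(c("de novo expression", "stable expression"), n_bg, TRUE,
                prob = c(0.3, 0.7))
  asg <- data.frame(probe_id = ids, gene_id = glab,
                    relation = "intragenic-host", distance = 0)
  cats2 <- stats::setNames(lab, glab)
  sel <- ids[c(which(lab == "de novo expression")[1:30],
               which(lab == "stable expression")[1:40])]
  r3 <- gene_category_enrichment(sel, ids, asg, cats2, n_sims = 4000,
                                 seed = 3)
  K <- sum(lab == "de novo expression")
  p_hg <- hypergeometric_tail(30, K, 70, n_bg)
  p_mc <- r3$p_enrich[r3$class == "de novo expression"]
  se <- sqrt(p_hg * (1 - p_hg) / 4000)
  expect_lt(abs(p_mc - p_hg), 3 * se + 1 / 4001)
})
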