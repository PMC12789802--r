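test_that("beta noise model recovers its target mean with bounded support", {
  set.seed(51)
  x <- simulate_beta(0.3, 100, 10000)
  se <- sd(x) / sqrt(10000)
  expect_lt(abs(mean(x) - 0.3), 3 * se)
  expect_true(all(x > 0 & x < 1))
  # large precision concentrates draws tightly around the mean
  y <- simulate_beta(0.5, 1e7, 1000)
  expect_true(all(abs(y - 0.5) < 0.01))
  expect_warning(simulate_beta(0, 10, 5), "clamped")
})

test_that("configuration validation rejects inconsistent class counts", {
  expect_error(simulation_config(contigs = c(chr1 = 5e5), n_cpgs = 2000),
               "sum\\(contigs\\)/500")
  expect_error(simulation_config(contigs = c(chr1 = 5e5, chr2 = 5e5),
                                 n_cpgs = 2000, n_genes = 200,
                                 n_active = 1500, n_nbc_hom = 300,
                                 n_nbc_het = 300),
               "genes")
  expect_error(simulation_config(contigs = c(chr1 = 5e5, chr2 = 5e5),
                                 n_cpgs = 2000, n_genes = 200,
                                 n_active = 60, n_accessible = 15,
                                 n_nbc_hom = 20, n_nbc_het = 30,
                                 n_drift = 500, n_bg_methylated = 1500),
               "exceed")
  expect_error(simulation_config(het_fraction = 1.2), "het_fraction")
})

test_that("same seed gives byte-identical datasets", {
  ds1 <- small_dataset()
  dir2 <- file.path(tempdir(), "mi_small_ds_rep")
  suppressMessages(generate_dataset(small_sim_config(), dir2))
  dir1 <- file.path(tempdir(), "mi_small_ds")
  # compare the freshly generated file set (dir1 may hold extra scratch
  # files written by other tests); the manifest holds absolute paths
  files <- setdiff(list.files(dir2, recursive = TRUE),
                   "truth/manifest.json")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("planted NBC-het CpGs have intermediate NBC means; drift CpGs fail the drift filter", {
  # run at the default scale: the per-population drift margin (generative
  # difference 0.22 vs threshold 0.25) carries ~2.7% per-CpG noise, so the
  # 95% bound needs the full 400 drift CpGs to be a stable property
  ds <- default_dataset()
  sheet <- read_sample_sheet(ds$paths$samples)
  beta <- read_beta_matrix(ds$paths$beta, sheet)
  truth <- ds$truth$cpg
  nbc_cols <- sheet$sample[sheet$assay == "methylation" &
                             sheet$population %in% c("NBC-B", "NBC-T")]
  het <- truth$probe_id[truth$class == "nbc_het"]
  het_means <- rowMeans(beta[het, nbc_cols])
  expect_true(all(het_means > 0.75 & het_means < 0.88))

  # drift CpGs: |mean(GCBC) - mean(cMCL)| < 0.25 for >= 95%
  g_cols <- sheet$sample[sheet$population == "GCBC" &
                           sheet$assay == "methylation"]
  c_cols <- sheet$sample[sheet$population == "cMCL" &
                           sheet$assay == "methylation"]
  drift <- truth$probe_id[truth$class == "drift"]
  diffs <- abs(rowMeans(beta[drift, g_cols]) - rowMeans(beta[drift, c_cols]))
  expect_gte(mean(diffs < 0.25), 0.95)
})

test_that("planted structure is internally consistent", {
  ds <- small_dataset()
  truth <- ds$truth$cpg
  cfg <- small_sim_config()
  expect_equal(sum(truth$class %in% c("active", "active_accessible")),
               cfg$n_active)
  expect_equal(sum(truth$class == "active_accessible"), cfg$n_accessible)
  expect_equal(sum(truth$class == "nbc_hom"), cfg$n_nbc_hom)
  expect_equal(sum(truth$class == "nbc_het"), cfg$n_nbc_het)
  # accessibility peaks cover exactly the planted accessible subset
  peaks <- read_bed_peaks(ds$paths$atac)
  pts <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(truth$pos + 1, width = 1))
  covered <- GenomicRanges::countOverlaps(pts, peaks) > 0
  expect_identical(covered, truth$class == "active_accessible")
  # every het CpG records the mixture fraction; others do not
  expect_true(all(!is.na(truth$het_fraction[truth$class == "nbc_het"])))
  expect_true(all(is.na(truth$het_fraction[truth$class != "nbc_het"])))
  # planted motifs sit inside the +/-50 bp window, off the CpG dinucleotide
  pl <- truth[!is.na(truth$motif_id), ]
  expect_true(all(pl$motif_offset >= -50 &
                    pl$motif_offset + cfg$motif_length - 1 <= 50))
  expect_true(all(pl$motif_offset + cfg$motif_length - 1 < 0 |
                    pl$motif_offset > 1))
  # inserted consensus is present in the genome at the recorded offset
  genome <- read_genome(ds$paths$genome)
  cons <- ds$truth$motif$consensus[match(pl$motif_id,
                                         ds$truth$motif$motif_id)]
  for (i in sample.int(nrow(pl), min(25, nrow(pl)))) {
    s <- as.character(Biostrings::subseq(
      genome[[pl$chrom[i]]], pl$pos[i] + 1 + pl$motif_offset[i],
      width = cfg$motif_length))
    expect_equal(s, cons[i])
  }
})
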