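# Shared fixtures, memoized per session so the expensive datasets and
# pipeline runs are built once and reused across test files.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = fixture_cache)) assign(key, fn(),
                                                  envir = fixture_cache)
  get(key, envir = fixture_cache)
}

small_sim_config <- function(seed = 42) {
  simulation_config(contigs = c(chr1 = 5e5, chr2 = 5e5), n_cpgs = 2000,
                    n_genes = 200, n_active = 60, n_accessible = 15,
                    n_nbc_hom = 20, n_nbc_het = 30, n_drift = 40,
                    n_bg_methylated = 600, seed = seed)
}

small_dataset <- function() memo("small_ds", function() {
  suppressMessages(generate_dataset(small_sim_config(),
                                    file.path(tempdir(), "mi_small_ds")))
})

# one small pipeline run, shared by the pipeline tests and the determinism
# criterion (which re-runs it with the same seed into a second directory)
small_run <- function() memo("small_run", function() {
  cfg <- pipeline_config_from_dataset(small_dataset(),
                                      file.path(tempdir(), "mi_small_run"),
                                      n_sims_chromatin = 2000,
                                      n_sims_genes = 2000, seed = 9)
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
})

# default study-scale dataset and pipeline run (acceptance conditions)
default_dataset <- function() memo("default_ds", function() {
  suppressMessages(generate_dataset(simulation_config(seed = 11),
                                    file.path(tempdir(), "mi_default_ds")))
})

default_run <- function() memo("default_run", function() {
  cfg <- pipeline_config_from_dataset(default_dataset(),
                                      file.path(tempdir(),
                                                "mi_default_run"),
                                      seed = 5)
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
})

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

# adjusted Rand index between two label vectors (standard contingency
# formula; used as the clustering-recovery metric)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# random but valid transcript models for the annotation-score property
random_gene_models <- function(n_tx = 120, contig_len = 1e6, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_tx), function(i) {
    chrom <- sample(c("chr1", "chr2"), 1)
    start <- sample.int(contig_len - 20000L, 1)
    n_ex <- sample(1:4, 1)
    # exon lengths and gaps
    el <- sample(100:600, n_ex, replace = TRUE)
    gap <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE) else
      integer(0)
    es <- start + cumsum(c(0L, el[-n_ex] + gap))
    ee <- es + el
    end <- max(ee)
    coding <- sample(c(0L, 1L), 1)
    cs <- if (coding) es[1] + min(50L, el[1] - 1L) else NA_integer_
    ce <- if (coding) ee[n_ex] - min(50L, el[n_ex] - 1L) else NA_integer_
    data.frame(transcript_id = sprintf("RT%03d", i),
               gene_id = sprintf("RG%03d", i),
               chrom = chrom, strand = sample(c("+", "-"), 1),
               start = start, end = end,
               exon_starts = I(list(as.integer(es))),
               exon_ends = I(list(as.integer(ee))),
               cds_start = cs, cds_end = ce, coding = coding)
  })
  do.call(rbind, rows)
}

random_windows <- function(n, width = 101, seed = 1) {
  set.seed(seed)
  Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, TRUE), collapse = ""), ""))
}

uniform_freqs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
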