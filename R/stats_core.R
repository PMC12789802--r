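# Shared statistical engine: scored-permutation enrichment, exact-test and
# multiple-testing utilities.

#' Monte-Carlo permutation enrichment test over class labels
#'
#' Simulates the null of no annotation-frequency difference between a
#' selected set and a background by repeated random sampling without
#' replacement from the background, with the sample size matched to the
#' selection.  A simulation scores 1 for enrichment of a class when its
#' count in the simulated sample is greater than or equal to the observed
#' count in the selection; depletion is scored symmetrically (less than or
#' equal).  P-values are `(r + 1) / (n + 1)`, counting the observed data as
#' one of the permutations.
#'
#' @param selected Vector of class labels of the selected items.
#' @param background Vector of class labels of the background items.
#' @param n_sims Number of random samplings (default 1e5).
#' @param seed Optional integer seed.
#' @return data.frame with one row per class: observed count, analytic
#'   expectation (`n * K / N`), permutation-mean expectation, fold change
#'   (observed / permutation mean; `Inf` when the mean is 0), exceedance
#'   counts `r_enrich`/`r_deplete`, `n_sims`, `p_enrich`, `p_deplete`.
#' @export
monte_carlo_enrichment <- function(selected, background, n_sims = 1e5,
                                   seed = NULL) {
  if (!length(selected) || !length(background))
    stop_format("empty selection or background")
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- union(unique(as.character(background)),
                   unique(as.character(selected)))
  K <- length(classes)
  obs <- tabulate(match(as.character(selected), classes), nbins = K)
  bg_codes <- match(as.character(background), classes)
  orphan <- setdiff(unique(as.character(selected)),
                    unique(as.character(background)))
  if (length(orphan))
    warning(sprintf("class(es) present in selection but absent from background: %s",
                    paste(orphan, collapse = ", ")))
  n <- length(selected)
  N <- length(background)
  r_en <- numeric(K); r_de <- numeric(K); tot <- numeric(K)
  for (s in seq_len(n_sims)) {
    cnt <- tabulate(bg_codes[sample.int(N, n)], nbins = K)
    r_en <- r_en + (cnt >= obs)
    r_de <- r_de + (cnt <= obs)
    tot <- tot + cnt
  }
  expected_mc <- tot / n_sims
  data.frame(class = classes,
             observed = obs,
             expected_analytic = n * tabulate(bg_codes, nbins = K) / N,
             expected = expected_mc,
             fold = ifelse(expected_mc > 0, obs / expected_mc,
                           ifelse(obs > 0, Inf, NA_real_)),
             r_enrich = r_en,
             r_deplete = r_de,
             n_sims = n_sims,
             p_enrich = (r_en + 1) / (n_sims + 1),
             p_deplete = (r_de + 1) / (n_sims + 1),
             row.names = NULL)
}

# Generic scored-permutation engine on a per-item weight matrix: the null
# statistic of a simulation is colSums over a size-matched random subset of
# background rows.  Shared by annotation_enrichment(); consumes the RNG in
# the same order as monte_carlo_enrichment (one sample.int per simulation),
# so the 0/1-weight case reduces exactly to the count case under one seed.
mc_enrichment_weights <- function(W_sel, W_bg, n_sims = 1e5, seed = NULL) {
  if (!nrow(W_sel) || !nrow(W_bg))
    stop_format("empty selection or background")
  stopifnot(identical(colnames(W_sel), colnames(W_bg)), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- colSums(W_sel)
  n <- nrow(W_sel); N <- nrow(W_bg); K <- ncol(W_bg)
  r_en <- numeric(K); r_de <- numeric(K); tot <- numeric(K)
  for (s in seq_len(n_sims)) {
    stat <- colSums(W_bg[sample.int(N, n), , drop = FALSE])
    r_en <- r_en + (stat >= obs)
    r_de <- r_de + (stat <= obs)
    tot <- tot + stat
  }
  expected_mc <- tot / n_sims
  data.frame(class = colnames(W_bg),
             observed = obs,
             expected_analytic = n * colSums(W_bg) / N,
             expected = expected_mc,
             fold = ifelse(expected_mc > 0, obs / expected_mc,
                           ifelse(obs > 0, Inf, NA_real_)),
             r_enrich = r_en, r_deplete = r_de, n_sims = n_sims,
             p_enrich = (r_en + 1) / (n_sims + 1),
             p_deplete = (r_de + 1) / (n_sims + 1),
             row.names = NULL)
}

#' Exact hypergeometric upper tail P(X >= k)
#'
#' Exact sum of the hypergeometric pmf from `k` to `min(n, K)`, accumulated
#' in log space.  Serves as the analytic oracle for the permutation test.
#'
#' @param k Observed count in the sample (values < 0 are treated as 0).
#' @param K Number of successes in the population.
#' @param n Sample size.
#' @param N Population size.
#' @return Upper-tail probability.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(K >= 0, K <= N, n >= 0, n <= N)
  k <- max(0, k)
  hi <- min(n, K)
  lo_support <- max(0, n - (N - K))
  if (k > hi) return(0)
  if (k <= lo_support) return(1)
  i <- seq.int(k, hi)
  lp <- stats::dhyper(i, K, N - K, n, log = TRUE)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio and two-sided p-value obtained
#' by summing the probabilities of all tables (margins fixed) as or less
#' probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_format("cells must be non-negative integers")
  if (sum(cells) == 0) stop_format("all-zero 2x2 table")
  ft <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_format("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Serialize enrichment results to TSV
#' @param res data.frame from an enrichment function.
#' @param path Output path.
#' @export
write_enrichment <- function(res, path) {
  data.table::fwrite(res, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
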