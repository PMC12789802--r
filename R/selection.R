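# Stage 1: population mean methylation, cMCL-specific CpG selection with
# proliferation-drift filtering, and within-category proximity clustering.

#' Selection thresholds
#'
#' Defaults follow the tumor/normal/drift constants used throughout the
#' analysis: tumor mean below 0.25, normal (NBC) mean above 0.75, and a
#' methylation difference greater than 0.25 between each highly
#' proliferative mature B-cell subtype (GCBC, MBC, PB/PC) and the tumor.
#'
#' @param tumor_max Upper bound (strict) on the tumor population mean.
#' @param normal_min Lower bound (strict) on the pooled NBC mean.
#' @param drift_min_diff Minimum (strict) difference between each drift
#'   population and the tumor.
#' @param drift_pops Populations used for the drift filter.
#' @return list of thresholds.
#' @export
selection_thresholds <- function(tumor_max = 0.25, normal_min = 0.75,
                                 drift_min_diff = 0.25,
                                 drift_pops = c("GCBC", "MBC", "PB/PC")) {
  stopifnot(tumor_max > 0, tumor_max < normal_min, normal_min < 1,
            drift_min_diff > 0)
  list(tumor_max = tumor_max, normal_min = normal_min,
       drift_min_diff = drift_min_diff, drift_pops = drift_pops)
}

#' Per-population mean beta values
#'
#' Missing values are excluded from means.  A probe missing in more than
#' `max_missing_frac` of a population's samples gets a missing mean for that
#' population (counted and reported via a message).  The NBC mean pools
#' NBC-B and NBC-T samples at the sample level; per-source means are also
#' reported.
#'
#' @param beta CpG x sample beta matrix.
#' @param sample_sheet Sample sheet (methylation assay rows are used).
#' @param max_missing_frac Missingness fraction strictly above which a
#'   (probe, population) mean is set missing (default 0.5).
#' @return list with `means` (CpG x population matrix, including a pooled
#'   `NBC` column) and `n_used` (matching matrix of sample counts).
#' @export
population_mean_beta <- function(beta, sample_sheet, max_missing_frac = 0.5) {
  meth <- sample_sheet[sample_sheet$assay == "methylation", , drop = FALSE]
  missing_cols <- setdiff(meth$sample, colnames(beta))
  if (length(missing_cols))
    stop_format("methylation sample(s) absent from beta matrix: %s",
                paste(missing_cols, collapse = ", "))
  pops <- split(meth$sample, meth$population)
  pops$NBC <- meth$sample[meth$population %in% c("NBC-B", "NBC-T")]
  means <- matrix(NA_real_, nrow(beta), length(pops),
                  dimnames = list(rownames(beta), names(pops)))
  n_used <- means
  n_dropped <- 0L
  for (p in names(pops)) {
    cols <- pops[[p]]
    if (!length(cols)) next
    sub <- beta[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    drop <- (length(cols) - n_ok) / length(cols) > max_missing_frac
    mu[drop | n_ok == 0] <- NA_real_
    n_dropped <- n_dropped + sum(drop & n_ok > 0)
    means[, p] <- mu
    n_used[, p] <- n_ok
  }
  if (n_dropped > 0)
    mi_log("selection", sprintf(
      "%d (probe, population) means dropped for > %.0f%% missingness",
      n_dropped, 100 * max_missing_frac))
  list(means = means, n_used = n_used)
}

#' Select cMCL-specific demethylated CpGs
#'
#' A CpG is selected iff (strict comparisons throughout) its cMCL mean is
#' below `tumor_max`, its pooled NBC mean is above `normal_min`, and for
#' each drift population the difference (population minus cMCL) exceeds
#' `drift_min_diff`.  CpGs with a missing required mean are excluded and
#' tallied.
#'
#' @param pop_means Result of [population_mean_beta()] (or its `means`
#'   matrix).
#' @param thresholds See [selection_thresholds()].
#' @param nbc_column Which column to use as the normal reference
#'   (default pooled `"NBC"`; set `"NBC-B"` for blood-only).
#' @return data.frame with probe_id, the relevant means, `selected` flag and
#'   a `reason` string (first failing rule, or "" when selected).
#' @export
select_cmcl_specific <- function(pop_means,
                                 thresholds = selection_thresholds(),
                                 nbc_column = "NBC") {
  means <- if (is.list(pop_means) && !is.null(pop_means$means))
    pop_means$means else pop_means
  need <- c("cMCL", nbc_column, thresholds$drift_pops)
  miss <- setdiff(need, colnames(means))
  if (length(miss))
    stop_format("population mean(s) missing: %s", paste(miss, collapse = ", "))
  n <- nrow(means)
  reason <- character(n)
  required_na <- rowSums(is.na(means[, need, drop = FALSE])) > 0
  reason[required_na] <- "missing_population_mean"
  ok <- !required_na
  fail_tumor <- ok & !(means[, "cMCL"] < thresholds$tumor_max)
  reason[fail_tumor] <- "cMCL_not_below_tumor_max"
  ok <- ok & !fail_tumor
  fail_nbc <- ok & !(means[, nbc_column] > thresholds$normal_min)
  reason[fail_nbc] <- "NBC_not_above_normal_min"
  ok <- ok & !fail_nbc
  for (p in thresholds$drift_pops) {
    fail <- ok & !(means[, p] - means[, "cMCL"] > thresholds$drift_min_diff)
    reason[fail] <- paste0("drift_filter_", gsub("/", "", p))
    ok <- ok & !fail
  }
  n_excl_missing <- sum(required_na)
  if (n_excl_missing)
    mi_log("selection", sprintf(
      "%d CpG(s) excluded for missing required population means",
      n_excl_missing))
  data.frame(probe_id = rownames(means),
             means[, need, drop = FALSE],
             selected = ok, reason = reason,
             row.names = NULL, check.names = FALSE)
}

#' Fraction of CpGs with a same-group neighbour within a window
#'
#' For each group, the fraction of its CpGs that have at least one other CpG
#' of the same group on the same contig at distance `<= window_bp`
#' (distance = absolute position difference).  Empty groups yield `NA`.
#'
#' @param chrom,pos Contig names and 0-based positions.
#' @param group Category labels (one per CpG).
#' @param window_bp Window size in bp (default 50).
#' @return data.frame with group, n and fraction.
#' @export
proximity_fraction <- function(chrom, pos, group, window_bp = 50) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(group))
  groups <- unique(as.character(group))
  rows <- lapply(groups, function(g) {
    sel <- which(group == g)
    if (!length(sel))
      return(data.frame(group = g, n = 0L, fraction = NA_real_))
    flagged <- logical(length(sel))
    for (ct in unique(chrom[sel])) {
      idx <- sel[chrom[sel] == ct]
      if (length(idx) < 2) next
      o <- order(pos[idx]); p <- pos[idx][o]
      d <- diff(p)
      close_next <- c(d <= window_bp, FALSE)
      close_prev <- c(FALSE, d <= window_bp)
      hit <- close_next | close_prev
      flagged[match(idx[o][hit], sel)] <- TRUE
    }
    data.frame(group = g, n = length(sel), fraction = mean(flagged))
  })
  do.call(rbind, rows)
}
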