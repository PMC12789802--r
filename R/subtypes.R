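# Stage 3: split inactive CpGs into NBC-het and NBC-hom by hierarchical
# clustering of their NBC methylation profiles, and report the
# best-separating methylation threshold.

#' Cluster inactive CpGs into NBC-het / NBC-hom
#'
#' Agglomerative hierarchical clustering of CpG rows over the NBC samples
#' (Euclidean distance, complete linkage -- the defaults of the standard
#' tool), cut into two clusters.  The cluster with the lower mean of
#' per-CpG NBC means is labelled NBC-het (slightly lowered bulk methylation,
#' candidate hidden-subpopulation imprint); the other NBC-hom.
#'
#' Missing values are imputed by the CpG row mean (logged).  If all rows are
#' identical the split is degenerate: everything is NBC-hom, with a warning.
#'
#' @param beta_nbc Matrix of inactive CpGs x NBC samples (probe ids as
#'   rownames).
#' @param method Agglomeration linkage (default "complete").
#' @param metric Distance metric (default "euclidean").
#' @return data.frame with probe_id, cluster, label, mean_nbc_beta; the
#'   clustering metadata (linkage, metric, mean silhouette width) is
#'   attached as attribute `metadata`.
#' @export
cluster_inactive_cpgs <- function(beta_nbc, method = "complete",
                                  metric = "euclidean") {
  stopifnot(is.matrix(beta_nbc))
  if (nrow(beta_nbc) < 2) stop_format("need at least 2 CpGs to cluster")
  if (anyNA(beta_nbc)) {
    n_imp <- sum(is.na(beta_nbc))
    rm <- rowMeans(beta_nbc, na.rm = TRUE)
    idx <- which(is.na(beta_nbc), arr.ind = TRUE)
    beta_nbc[idx] <- rm[idx[, 1]]
    mi_log("subtypes", sprintf("imputed %d missing value(s) by row mean",
                               n_imp))
  }
  row_means <- rowMeans(beta_nbc)
  d <- stats::dist(beta_nbc, method = metric)
  if (max(d) == 0) {
    warning("all NBC profiles identical; degenerate split, all NBC-hom")
    out <- data.frame(probe_id = rownames(beta_nbc), cluster = 1L,
                      label = "NBC-hom", mean_nbc_beta = row_means,
                      row.names = NULL)
    attr(out, "metadata") <- list(method = method, metric = metric,
                                  mean_silhouette = NA_real_)
    return(out)
  }
  hc <- stats::hclust(d, method = method)
  cl <- stats::cutree(hc, k = 2)
  cl_means <- tapply(row_means, cl, mean)
  het_cluster <- as.integer(names(which.min(cl_means)))
  label <- ifelse(cl == het_cluster, "NBC-het", "NBC-hom")
  sil <- tryCatch(mean(cluster::silhouette(cl, d)[, "sil_width"]),
                  error = function(e) NA_real_)
  out <- data.frame(probe_id = rownames(beta_nbc), cluster = unname(cl),
                    label = unname(label), mean_nbc_beta = unname(row_means),
                    row.names = NULL)
  attr(out, "metadata") <- list(method = method, metric = metric,
                                mean_silhouette = sil)
  out
}

#' Best-splitting methylation threshold between NBC-het and NBC-hom
#'
#' Finds the threshold t minimising misclassification of the labels by the
#' rule (mean NBC beta < t => NBC-het).  Candidate thresholds are the
#' midpoints of consecutive distinct observed means; among minimisers the
#' midpoint of the tightest bracketing pair is returned.
#'
#' @param mean_nbc_beta Per-CpG mean NBC beta values.
#' @param labels Matching labels, "NBC-het" / "NBC-hom".
#' @return list with `threshold` and `n_errors`.
#' @export
best_split_threshold <- function(mean_nbc_beta, labels) {
  stopifnot(length(mean_nbc_beta) == length(labels))
  if (length(unique(labels)) < 2)
    stop_format("both labels must be present")
  u <- sort(unique(mean_nbc_beta))
  if (length(u) < 2) stop_format("all means identical; no split exists")
  mids <- (u[-1] + u[-length(u)]) / 2
  gaps <- diff(u)
  is_het <- labels == "NBC-het"
  errs <- vapply(mids, function(t) {
    sum(is_het & mean_nbc_beta >= t) + sum(!is_het & mean_nbc_beta < t)
  }, numeric(1))
  best <- which(errs == min(errs))
  pick <- best[which.min(gaps[best])]
  list(threshold = mids[pick], n_errors = errs[pick])
}
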