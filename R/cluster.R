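# Clustering of DMR methylation trajectories across the three stages
# (P0.5 prospermatogonia, P7.5 Kit- spermatogonia, P7.5 Kit+
# spermatogonia) into archetype groups.

#' Build the DMR trajectory matrix
#'
#' One row per DMR with the level in the first stage (`l0`) and the
#' changes across the two transitions (`d1` = stage2 - stage1, `d2` =
#' stage3 - stage2), all in percentage points. The telescoping identity
#' l0 + d1 + d2 recovers the final-stage level. DMRs whose level is
#' undefined in any stage are dropped with a warning.
#'
#' @param dmrs DMR data.frame with `chrom`, `start`, `end`.
#' @param methylomes ordered list of three pooled, filtered CG call
#'   tables (first stage, middle stage, last stage).
#' @return data.frame `dmr` (row index into `dmrs`), `l0`, `d1`, `d2`.
#' @export
build_trajectories <- function(dmrs, methylomes) {
  stopifnot(length(methylomes) == 3L)
  levels <- vapply(methylomes, function(calls) {
    vapply(seq_len(nrow(dmrs)), function(i) {
      methylation_level(calls, region = dmrs[i, ], context = "CG")
    }, numeric(1))
  }, numeric(nrow(dmrs)))
  levels <- matrix(levels, nrow = nrow(dmrs)) * 100
  ok <- stats::complete.cases(levels)
  if (any(!ok)) {
    warning(sum(!ok), " DMR(s) dropped: level missing in some stage")
  }
  data.frame(dmr = which(ok), l0 = levels[ok, 1L],
             d1 = levels[ok, 2L] - levels[ok, 1L],
             d2 = levels[ok, 3L] - levels[ok, 2L])
}

trajectory_columns <- function(mat) {
  as.matrix(as.data.frame(mat)[, c("l0", "d1", "d2")])
}

#' Cluster DMR trajectories by complete-linkage hierarchical clustering
#'
#' Euclidean distance on the unscaled (l0, d1, d2) rows, complete
#' linkage, dendrogram cut into `k` groups. Raw dendrogram labels are
#' arbitrary, so clusters are renumbered canonically by sorting their
#' mean trajectories lexicographically in descending (l0, d1, d2) order:
#' high-start/stable/late-loss archetypes come first, low-start/late-gain
#' archetypes last. This makes labels reproducible and
#' permutation-invariant.
#'
#' @param mat trajectory matrix (data.frame with `l0`, `d1`, `d2`, or a
#'   3-column matrix).
#' @param k number of clusters (default 6).
#' @return integer cluster labels (1..k) with the per-cluster mean
#'   trajectories attached as attribute `"means"`.
#' @export
cluster_trajectories <- function(mat, k = 6L) {
  x <- trajectory_columns(mat)
  if (nrow(x) < k) stop("k exceeds the number of DMR trajectories")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  raw <- stats::cutree(hc, k = k)
  means <- t(vapply(seq_len(k), function(g) colMeans(x[raw == g, ,
                                                       drop = FALSE]),
                    numeric(3L)))
  ord <- order(-means[, 1L], -means[, 2L], -means[, 3L])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[raw]
  out_means <- means[ord, , drop = FALSE]
  dimnames(out_means) <- list(seq_len(k), c("l0", "d1", "d2"))
  structure(labels, means = out_means)
}

#' Select the cluster count by mean silhouette width
#'
#' Cuts the same complete-linkage dendrogram at each k in `k_range` and
#' returns the k maximizing the mean silhouette width (Euclidean
#' distance). A maximum below `flag_below` is flagged: the data carry
#' little cluster structure and the chosen k is not meaningful. The
#' default threshold 0.4 sits between the mean silhouette of a single
#' multivariate Gaussian blob under this linkage (about 0.3) and that
#' of genuinely separated trajectory archetypes (0.5 and above).
#'
#' @param mat trajectory matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param flag_below silhouette threshold for the structure flag
#'   (default 0.4).
#' @return list with `k`, `silhouette` (named vector of mean widths),
#'   and `structure` (FALSE when the best silhouette < `flag_below`).
#' @export
select_k_silhouette <- function(mat, k_range = 2:10, flag_below = 0.4) {
  x <- trajectory_columns(mat)
  k_range <- k_range[k_range >= 2L & k_range <= nrow(x) - 1L]
  if (!length(k_range)) stop("no admissible k in range")
  d <- stats::dist(x, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  widths <- vapply(k_range, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k = k), d)[, "sil_width"])
  }, numeric(1))
  names(widths) <- k_range
  best <- k_range[which.max(widths)]
  list(k = best, silhouette = widths,
       structure = max(widths) >= flag_below)
}
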