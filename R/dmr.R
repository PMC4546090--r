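# Stage-specific DMR calling: sliding 500-bp windows over strand-merged,
# coverage-filtered CG calls, Welch tests on per-site fraction vectors,
# genome-wide Benjamini-Hochberg correction, joint effect-size and
# significance thresholds, and direction-stratified merging.

#' Enumerate candidate DMR windows between two stages
#'
#' Slides windows of `window` bp at `step`-bp intervals along each
#' chromosome. A window qualifies when it contains at least `min_sites`
#' CG sites covered at least `min_coverage` times in *both* stages (the
#' same site set enters both per-site fraction vectors). Per-window
#' statistics: the pooled-read level of each stage, their difference in
#' percentage points (`delta` = stage B - stage A), and the mean/variance
#' of the per-site fractions feeding the Welch test.
#'
#' @param calls_a,calls_b strand-merged, coverage-filtered CG call tables
#'   (replicates pooled with [pool_replicates()]).
#' @param window window size in bp (default 500).
#' @param step sliding step in bp (default 100).
#' @param min_sites minimum qualifying CG sites per window (default 5).
#' @param min_coverage minimum per-site coverage in each stage (default
#'   10).
#' @return data.frame of candidate windows with per-stage levels,
#'   `delta`, and per-site summary statistics.
#' @export
enumerate_dmr_windows <- function(calls_a, calls_b, window = 500L,
                                  step = 100L, min_sites = 5L,
                                  min_coverage = 10L) {
  a <- data.table::as.data.table(calls_a)[context == "CG"]
  b <- data.table::as.data.table(calls_b)[context == "CG"]
  sites <- merge(a[, .(chrom, pos, m_a = n_meth, t_a = n_total)],
                 b[, .(chrom, pos, m_b = n_meth, t_b = n_total)],
                 by = c("chrom", "pos"))
  sites <- sites[sites$t_a >= min_coverage & sites$t_b >= min_coverage]
  data.table::setorder(sites, chrom, pos)
  pieces <- lapply(split(sites, sites$chrom), function(sub) {
    pos <- sub$pos
    n <- length(pos)
    if (n < min_sites) return(NULL)
    starts <- seq.int(max(0L, (min(pos) %/% step) * step - (window - step)),
                      max(pos), by = step)
    lo <- findInterval(starts - 0.5, pos) + 1L
    hi <- findInterval(starts + window - 0.5, pos)
    n_sites <- pmax(0L, hi - lo + 1L)
    keep <- n_sites >= min_sites
    if (!any(keep)) return(NULL)
    lo <- lo[keep]; hi <- hi[keep]; starts <- starts[keep]
    n_sites <- n_sites[keep]
    f_a <- sub$m_a / sub$t_a
    f_b <- sub$m_b / sub$t_b
    rngsum <- function(x) {
      cs <- cumsum(as.numeric(x))
      cs[hi] - ifelse(lo > 1L, cs[pmax(lo - 1L, 1L)], 0)
    }
    sum_fa <- rngsum(f_a); sum_fa2 <- rngsum(f_a^2)
    sum_fb <- rngsum(f_b); sum_fb2 <- rngsum(f_b^2)
    mean_a <- sum_fa / n_sites
    mean_b <- sum_fb / n_sites
    var_a <- pmax(0, (sum_fa2 - n_sites * mean_a^2) / (n_sites - 1L))
    var_b <- pmax(0, (sum_fb2 - n_sites * mean_b^2) / (n_sites - 1L))
    level_a <- rngsum(sub$m_a) / rngsum(sub$t_a)
    level_b <- rngsum(sub$m_b) / rngsum(sub$t_b)
    data.frame(chrom = sub$chrom[1L], start = starts,
               end = starts + window, n_sites = n_sites,
               level_a = level_a, level_b = level_b,
               delta = 100 * (level_b - level_a),
               mean_a = mean_a, mean_b = mean_b,
               var_a = var_a, var_b = var_b)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      level_a = numeric(), level_b = numeric(),
                      delta = numeric(), mean_a = numeric(),
                      mean_b = numeric(), var_a = numeric(),
                      var_b = numeric())
  }
  rownames(out) <- NULL
  out
}

# Vectorized Welch statistic from group summaries. Degenerate case (both
# variances zero): p = 0 when the means differ (every site pair differs
# in the same direction), p = 1 when equal.
welch_from_summaries <- function(mean_a, var_a, n_a, mean_b, var_b, n_b) {
  se2 <- var_a / n_a + var_b / n_b
  t_stat <- (mean_b - mean_a) / sqrt(se2)
  df <- se2^2 / ((var_a / n_a)^2 / (n_a - 1) + (var_b / n_b)^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(mean_a[degen] == mean_b[degen], 1, 0)
    t_stat[degen] <- ifelse(mean_a[degen] == mean_b[degen], 0,
                            sign(mean_b[degen] - mean_a[degen]) * Inf)
    df[degen] <- NA_real_
  }
  list(statistic = t_stat, df = df, p_value = p)
}

#' Welch two-sample t-test on per-site methylation fractions
#'
#' The unequal-variance (Welch) t-test comparing the per-CG-site
#' methylation fractions of one window between two stages. When both
#' groups have zero variance the statistic is undefined; p is set to 0
#' if the group means differ (every site differs in the same direction)
#' and 1 otherwise.
#'
#' @param frac_a,frac_b numeric vectors of per-site fractions (length >=
#'   2 each; the DMR screen requires >= 5).
#' @return list with `statistic`, `df`, `p_value` (two-sided), and
#'   `delta` (difference of site means, B - A, in percentage points).
#' @export
welch_site_test <- function(frac_a, frac_b) {
  stopifnot(length(frac_a) >= 2L, length(frac_b) >= 2L)
  res <- welch_from_summaries(mean(frac_a), stats::var(frac_a),
                              length(frac_a),
                              mean(frac_b), stats::var(frac_b),
                              length(frac_b))
  res$delta <- 100 * (mean(frac_b) - mean(frac_a))
  res
}

#' Test all candidate windows
#'
#' Adds the Welch statistic, degrees of freedom, two-sided p-value, and
#' the genome-wide Benjamini-Hochberg q-value to a candidate-window
#' table. BH is applied once across all eligible windows of the
#' comparison, not per chromosome.
#'
#' @param candidates output of [enumerate_dmr_windows()].
#' @return `candidates` with `statistic`, `df`, `p_value`, `q_value`.
#' @export
test_dmr_windows <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$statistic <- numeric(0)
    candidates$df <- numeric(0)
    candidates$p_value <- numeric(0)
    candidates$q_value <- numeric(0)
    return(candidates)
  }
  res <- welch_from_summaries(candidates$mean_a, candidates$var_a,
                              candidates$n_sites, candidates$mean_b,
                              candidates$var_b, candidates$n_sites)
  candidates$statistic <- res$statistic
  candidates$df <- res$df
  candidates$p_value <- res$p_value
  candidates$q_value <- adjust_bh(res$p_value)
  candidates
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in \[0, 1\].
#' @return monotone, order-preserving q-values in \[0, 1\].
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Call DMRs from tested windows
#'
#' A window is significant when |delta| exceeds `delta_threshold`
#' percentage points, p < `p_threshold`, and q < `q_threshold`, jointly.
#' Overlapping significant windows of the same direction are merged into
#' maximal runs (gain and loss runs merged separately; half-open
#' intervals, so abutting windows are not merged). Per-stage DMR levels
#' are recomputed as pooled-read levels over the merged interval when
#' call tables are supplied.
#'
#' @param tested output of [test_dmr_windows()].
#' @param delta_threshold minimum |delta| in percentage points (default
#'   30, exclusive).
#' @param p_threshold p-value cutoff (default 0.02, exclusive).
#' @param q_threshold FDR cutoff (default 0.05, exclusive).
#' @param calls_a,calls_b optional pooled call tables for recomputing
#'   merged-interval levels; otherwise coverage-weighted window levels
#'   are reused.
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `direction`
#'   (`"gain"`/`"loss"` in stage B relative to A), `level_a`, `level_b`,
#'   `delta`, `q_min`, `n_windows`.
#' @export
call_dmrs <- function(tested, delta_threshold = 30, p_threshold = 0.02,
                      q_threshold = 0.05, calls_a = NULL, calls_b = NULL) {
  sig <- tested[abs(tested$delta) > delta_threshold &
                  tested$p_value < p_threshold &
                  tested$q_value < q_threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      level_a = numeric(), level_b = numeric(),
                      delta = numeric(), q_min = numeric(),
                      n_windows = integer())
  if (nrow(sig) == 0L) return(empty)
  sig$direction <- ifelse(sig$delta > 0, "gain", "loss")
  merged <- lapply(split(sig, list(sig$chrom, sig$direction), drop = TRUE),
                   function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, sub$start[-1L] >= cummax(sub$end[-nrow(sub)])))
    do.call(rbind, lapply(split(sub, grp), function(run) {
      data.frame(chrom = run$chrom[1L], start = min(run$start),
                 end = max(run$end), direction = run$direction[1L],
                 level_a = sum(run$level_a * run$n_sites) /
                   sum(run$n_sites),
                 level_b = sum(run$level_b * run$n_sites) /
                   sum(run$n_sites),
                 q_min = min(run$q_value), n_windows = nrow(run))
    }))
  })
  dmrs <- do.call(rbind, merged)
  if (!is.null(calls_a) && !is.null(calls_b)) {
    dmrs$level_a <- vapply(seq_len(nrow(dmrs)), function(i) {
      methylation_level(calls_a, region = dmrs[i, ], context = "CG")
    }, numeric(1))
    dmrs$level_b <- vapply(seq_len(nrow(dmrs)), function(i) {
      methylation_level(calls_b, region = dmrs[i, ], context = "CG")
    }, numeric(1))
  }
  dmrs$delta <- 100 * (dmrs$level_b - dmrs$level_a)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start),
               c("chrom", "start", "end", "direction", "level_a",
                 "level_b", "delta", "q_min", "n_windows")]
  rownames(dmrs) <- NULL
  dmrs
}

#' Run the full DMR screen between two stages
#'
#' Convenience wrapper: enumerate candidate windows, Welch-test them,
#' BH-adjust genome-wide, threshold, and merge.
#'
#' @inheritParams enumerate_dmr_windows
#' @inheritParams call_dmrs
#' @return list with `dmrs` and the tested `windows` table.
#' @export
find_dmrs <- function(calls_a, calls_b, window = 500L, step = 100L,
                      min_sites = 5L, min_coverage = 10L,
                      delta_threshold = 30, p_threshold = 0.02,
                      q_threshold = 0.05) {
  cand <- enumerate_dmr_windows(calls_a, calls_b, window, step, min_sites,
                                min_coverage)
  tested <- test_dmr_windows(cand)
  dmrs <- call_dmrs(tested, delta_threshold, p_threshold, q_threshold,
                    calls_a = calls_a, calls_b = calls_b)
  list(dmrs = dmrs, windows = tested)
}

#' Classify DMR genomic locations
#'
#' Labels each DMR `promoter`, `exon`, `intron`, or `intergenic` by
#' overlap with gene annotation, with priority promoter > exon > intron >
#' intergenic. Promoters follow [promoter_intervals()] (2000 bp upstream
#' to 500 bp downstream of the TSS); the gene body between TSS and TES
#' counts as intron unless an exon table is supplied.
#'
#' @param dmrs DMR data.frame.
#' @param genes gene models.
#' @param exons optional data.frame of exon intervals (`chrom`, `start`,
#'   `end`).
#' @return character vector of location labels aligned to `dmrs` rows.
#' @export
classify_dmr_location <- function(dmrs, genes, exons = NULL) {
  if (nrow(dmrs) == 0L) return(character(0))
  labels <- rep("intergenic", nrow(dmrs))
  overlaps_any <- function(intervals) {
    if (is.null(intervals) || nrow(intervals) == 0L) {
      return(rep(FALSE, nrow(dmrs)))
    }
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(dmrs$chrom,
                             IRanges::IRanges(dmrs$start + 1L, dmrs$end)),
      GenomicRanges::GRanges(intervals$chrom,
                             IRanges::IRanges(intervals$start + 1L,
                                              intervals$end))
    )
    seq_len(nrow(dmrs)) %in% S4Vectors::queryHits(hits)
  }
  bodies <- data.frame(chrom = genes$chrom,
                       start = pmin(genes$start, genes$end),
                       end = pmax(genes$start, genes$end))
  labels[overlaps_any(bodies)] <- "intron"
  labels[overlaps_any(exons)] <- "exon"
  labels[overlaps_any(promoter_intervals(genes))] <- "promoter"
  labels
}

#' DMRs overlapping promoters
#'
#' @param dmrs DMR data.frame.
#' @param genes gene models.
#' @return the subset of `dmrs` classified as promoter DMRs.
#' @export
dmr_promoter_overlap <- function(dmrs, genes) {
  dmrs[classify_dmr_location(dmrs, genes) == "promoter", , drop = FALSE]
}
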