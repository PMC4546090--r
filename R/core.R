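# Site filtering, strand merging, conversion correction, and methylation
# levels at site/window/region/context resolution.

copy_tags <- function(df, template) {
  for (tag in c("assay", "compartment", "stage", "replicate")) {
    attr(df, tag) <- attr(template, tag)
  }
  df
}

#' Merge symmetric CpG records across strands
#'
#' A CpG dyad is read on both strands: the plus-strand cytosine at
#' position p and the minus-strand cytosine at p + 1. For strand-free CG
#' analysis their counts are combined into one record at p with strand
#' `"*"`. Unpaired CG records are kept as single-strand records (also
#' repositioned to their dyad coordinate); CH records pass through
#' unchanged.
#'
#' @param calls a stranded cytosine call table.
#' @return call table whose CG records are strand-merged.
#' @export
merge_symmetric_cg <- function(calls) {
  dt <- data.table::as.data.table(calls)
  cg <- dt[context == "CG"]
  ch <- dt[context != "CG"]
  if (nrow(cg)) {
    cg[, dyad := ifelse(strand == "+", pos, pos - 1L)]
    merged <- cg[, .(
      strand = "*",
      context = "CG",
      n_meth = sum(n_meth),
      n_total = sum(n_total)
    ), by = .(chrom, pos = dyad)]
    if (!is.null(dt$dinucleotide)) merged[, "dinucleotide" := "CG"]
  } else {
    merged <- cg[, c("chrom", "pos", "strand", "context", "n_meth",
                     "n_total"), with = FALSE]
  }
  out <- data.table::rbindlist(list(merged, ch), use.names = TRUE,
                               fill = TRUE)
  data.table::setorder(out, chrom, pos)
  copy_tags(as.data.frame(out), calls)
}

#' Coverage-filter a call table
#'
#' Retains CG records covered at least `min_cg` times, CH (CHG/CHH)
#' records covered at least `min_ch` times, and discards any record
#' covered by more than `max_cov` reads. CG records are expected to be
#' strand-merged first so the CG threshold applies to dyad coverage.
#'
#' @param calls call table (CG records strand-merged).
#' @param min_cg minimum CG coverage (default 6).
#' @param min_ch minimum CH coverage (default 4).
#' @param max_cov maximum coverage; records above it are discarded as
#'   likely collapsed repeats (default 100).
#' @return filtered call table. Filtering is idempotent.
#' @export
filter_by_coverage <- function(calls, min_cg = 6L, min_ch = 4L,
                               max_cov = 100L) {
  is_cg <- calls$context == "CG"
  keep <- calls$n_total <= max_cov &
    ((is_cg & calls$n_total >= min_cg) | (!is_cg & calls$n_total >= min_ch))
  copy_tags(calls[keep, , drop = FALSE], calls)
}

#' Estimate the bisulfite nonconversion rate from an unmethylated spike-in
#'
#' The lambda spike-in is fully unmethylated by construction, so every
#' methylated call is a conversion failure. The pooled rate
#' sum(n_meth)/sum(n_total) over all spike-in cytosines estimates the
#' nonconversion (conversion failure) rate; the conversion rate is
#' 1 minus this value.
#'
#' @param spike_calls spike-in call table.
#' @return nonconversion rate in \[0, 1\].
#' @export
estimate_nonconversion <- function(spike_calls) {
  if (nrow(spike_calls) == 0L || sum(spike_calls$n_total) == 0L) {
    stop("spike-in table is empty; nonconversion rate cannot be estimated")
  }
  sum(spike_calls$n_meth) / sum(spike_calls$n_total)
}

#' Correct an observed methylation level for bisulfite nonconversion
#'
#' Failures occur at random among truly unmethylated cytosines, so the
#' observed level mixes the true level t with the failure rate r:
#' observed = t + (1 - t) r. This inverts the mixture,
#' (observed - r) / (1 - r), clamped at 0.
#'
#' @param observed observed level(s) in \[0, 1\] (vectorized).
#' @param rate nonconversion rate in \[0, 1).
#' @return corrected level(s), never exceeding `observed`.
#' @export
correct_nonconversion <- function(observed, rate) {
  if (any(rate >= 1) || any(rate < 0)) stop("rate must be in [0, 1)")
  pmax(0, (observed - rate) / (1 - rate))
}

#' Pooled-read methylation level
#'
#' sum(n_meth)/sum(n_total) over qualifying records — the read-weighted
#' level conventionally reported for WGBS, not the mean of per-site
#' fractions.
#'
#' @param calls filtered call table.
#' @param region optional list/row with `chrom`, `start`, `end` (0-based
#'   half-open) restricting the records; whole table when `NULL`.
#' @param context optional context restriction: `"CG"`, `"CH"` (CHG and
#'   CHH), `"CHG"`, or `"CHH"`.
#' @return fraction in \[0, 1\], or `NA` when no record qualifies.
#' @export
methylation_level <- function(calls, region = NULL, context = NULL) {
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(region)) {
    keep <- keep & calls$chrom == region$chrom &
      calls$pos >= region$start & calls$pos < region$end
  }
  if (!is.null(context)) {
    keep <- keep & (if (context == "CH") calls$context %in% c("CHG", "CHH")
                    else calls$context == context)
  }
  tot <- sum(calls$n_total[keep])
  if (tot == 0L) return(NA_real_)
  sum(calls$n_meth[keep]) / tot
}

#' Per-context breakdown of methylated cytosines
#'
#' Partitions all assayed cytosines into methylated-at-CG,
#' methylated-at-CH, and unmethylated, after nonconversion correction of
#' the per-context levels. Each context's contribution is its corrected
#' level weighted by that context's share of total reads, so the three
#' fractions sum to 1. When a `dinucleotide` column is present, corrected
#' per-dinucleotide CH levels (CA/CT/CC) are reported as well.
#'
#' @param calls filtered call table covering CG and CH sites.
#' @param nonconversion_rate rate from [estimate_nonconversion()]
#'   (0 for no correction).
#' @return list with `meth_cg`, `meth_ch`, `unmeth` (summing to 1),
#'   per-context corrected levels `level_cg`, `level_ch`, and optional
#'   `dinucleotide_levels`.
#' @export
context_breakdown <- function(calls, nonconversion_rate = 0) {
  is_cg <- calls$context == "CG"
  tot_all <- sum(calls$n_total)
  if (tot_all == 0L) stop("empty call table")
  share_cg <- sum(calls$n_total[is_cg]) / tot_all
  share_ch <- 1 - share_cg
  lev <- function(mask) {
    t <- sum(calls$n_total[mask])
    if (t == 0L) return(0)
    correct_nonconversion(sum(calls$n_meth[mask]) / t, nonconversion_rate)
  }
  level_cg <- lev(is_cg)
  level_ch <- lev(!is_cg)
  meth_cg <- level_cg * share_cg
  meth_ch <- level_ch * share_ch
  out <- list(meth_cg = meth_cg, meth_ch = meth_ch,
              unmeth = 1 - meth_cg - meth_ch,
              level_cg = level_cg, level_ch = level_ch)
  if (!is.null(calls$dinucleotide)) {
    dins <- c("CA", "CT", "CC")
    out$dinucleotide_levels <- setNames(
      vapply(dins, function(d) lev(!is_cg & calls$dinucleotide %in% d),
             numeric(1)),
      dins
    )
  }
  out
}

#' Pooled methylation levels in genomic windows
#'
#' Computes the pooled-read level in fixed-size windows (tiling when
#' `step == size`, sliding otherwise) along each chromosome. Windows with
#' fewer than `min_sites` qualifying sites get `NA` levels but stay in
#' the track so tracks over the same grid align row-by-row.
#'
#' @param calls filtered call table (restrict `context` first if needed).
#' @param size window size in bp.
#' @param step step between window starts in bp (default `size`).
#' @param min_sites minimum sites for a defined level (default 1).
#' @param context optional context restriction as in
#'   [methylation_level()].
#' @param chrom_lengths optional named vector of chromosome lengths; the
#'   grid otherwise extends to the last covered site.
#' @return data.frame track: `chrom`, `start`, `end`, `level`, `n_sites`,
#'   `n_reads`, with `size` and `step` attributes.
#' @export
window_levels <- function(calls, size, step = size, min_sites = 1L,
                          context = NULL, chrom_lengths = NULL) {
  if (step > size) stop("step must not exceed window size")
  if (step < 1L) stop("step must be >= 1")
  if (!is.null(context)) {
    keep <- if (context == "CH") calls$context %in% c("CHG", "CHH")
            else calls$context == context
    calls <- calls[keep, , drop = FALSE]
  }
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else sort(unique(calls$chrom))
  pieces <- lapply(chroms, function(cc) {
    sub <- calls[calls$chrom == cc, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    max_extent <- if (!is.null(chrom_lengths)) chrom_lengths[[cc]]
                  else if (nrow(sub)) max(sub$pos) + 1L else 0L
    if (max_extent < 1L) return(NULL)
    starts <- seq.int(0L, max(0L, max_extent - 1L), by = step)
    stats <- pooled_window_stats(sub$pos, sub$n_meth, sub$n_total,
                                 starts, size)
    data.frame(chrom = cc, start = starts, end = pmin(starts + size,
                                                      max_extent),
               level = ifelse(stats$n_sites >= min_sites, stats$level,
                              NA_real_),
               n_sites = stats$n_sites, n_reads = stats$n_reads)
  })
  track <- do.call(rbind, pieces)
  if (is.null(track)) {
    track <- data.frame(chrom = character(), start = integer(),
                        end = integer(), level = numeric(),
                        n_sites = integer(), n_reads = integer())
  }
  attr(track, "size") <- size
  attr(track, "step") <- step
  track
}

# Windowed pooled sums over sorted positions via cumulative sums.
pooled_window_stats <- function(pos, n_meth, n_total, starts, size) {
  if (length(pos) == 0L) {
    z <- rep(0L, length(starts))
    return(list(n_sites = z, n_reads = z, level = rep(NA_real_,
                                                      length(starts))))
  }
  cs_m <- cumsum(as.numeric(n_meth))
  cs_t <- cumsum(as.numeric(n_total))
  lo <- findInterval(starts - 0.5, pos) + 1L
  hi <- findInterval(starts + size - 0.5, pos)
  n_sites <- pmax(0L, hi - lo + 1L)
  base_m <- ifelse(lo > 1L, cs_m[pmax(lo - 1L, 1L)], 0)
  base_t <- ifelse(lo > 1L, cs_t[pmax(lo - 1L, 1L)], 0)
  sum_m <- ifelse(n_sites > 0, cs_m[pmax(hi, 1L)] - base_m, 0)
  sum_t <- ifelse(n_sites > 0, cs_t[pmax(hi, 1L)] - base_t, 0)
  list(n_sites = n_sites, n_reads = sum_t,
       level = ifelse(sum_t > 0, sum_m / sum_t, NA_real_))
}

#' Correlate two window tracks
#'
#' Joins two tracks on their (chrom, start) grid, drops pairs where
#' either level is missing, and returns the correlation over complete
#' pairs.
#'
#' @param track_a,track_b window tracks over the same grid.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient, or `NA` with fewer than 3 complete
#'   pairs.
#' @export
correlate_windows <- function(track_a, track_b, method = "pearson") {
  merged <- merge(track_a[, c("chrom", "start", "level")],
                  track_b[, c("chrom", "start", "level")],
                  by = c("chrom", "start"), suffixes = c("_a", "_b"))
  ok <- stats::complete.cases(merged$level_a, merged$level_b)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(merged$level_a[ok], merged$level_b[ok], method = method)
}

#' Pool replicate call tables at the count level
#'
#' Sums read counts across replicates by (chrom, pos, strand, context),
#' so per-site fractions downstream reflect all reads of a stage.
#'
#' @param tables list of call tables from the same stage/assay.
#' @return pooled call table.
#' @export
pool_replicates <- function(tables) {
  dt <- data.table::rbindlist(lapply(tables, data.table::as.data.table),
                              use.names = TRUE, fill = TRUE)
  out <- if (!is.null(dt$dinucleotide)) {
    dt[, .(n_meth = sum(n_meth), n_total = sum(n_total),
           dinucleotide = dinucleotide[1L]),
       by = .(chrom, pos, strand, context)]
  } else {
    dt[, .(n_meth = sum(n_meth), n_total = sum(n_total)),
       by = .(chrom, pos, strand, context)]
  }
  data.table::setorder(out, chrom, pos)
  res <- as.data.frame(out)
  copy_tags(res, tables[[1]])
}
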