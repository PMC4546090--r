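# Regulatory-domain gene association: basal-plus-extension regulatory
# domains, DMR-to-gene linking, expression-change classification, and
# the enrichment test for expression change among DMR-linked genes.

#' Build basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain from `basal_upstream` bp
#' upstream to `basal_downstream` bp downstream of the TSS (defaults 5 kb
#' and 1 kb). The basal domain is then extended in both directions up to
#' `max_extension` bp from the TSS (default 1 Mb), truncated at the
#' nearest neighboring gene's basal domain boundary, but never below the
#' gene's own basal domain. Construction is deterministic and
#' order-independent.
#'
#' @param genes gene models (with `tss`, `strand`).
#' @param basal_upstream,basal_downstream basal extents in bp.
#' @param max_extension distal cap in bp from the TSS.
#' @return data.frame per gene: `id`, `chrom`, `basal_start`,
#'   `basal_end`, `start`, `end` (the extended interval).
#' @export
build_regulatory_domains <- function(genes, basal_upstream = 5000L,
                                     basal_downstream = 1000L,
                                     max_extension = 1e6) {
  plus <- genes$strand == "+"
  basal_start <- pmax(0, ifelse(plus, genes$tss - basal_upstream,
                                genes$tss - basal_downstream))
  basal_end <- ifelse(plus, genes$tss + basal_downstream,
                      genes$tss + basal_upstream)
  dom <- data.frame(id = genes$id, chrom = genes$chrom, tss = genes$tss,
                    basal_start = basal_start, basal_end = basal_end)
  pieces <- lapply(split(dom, dom$chrom), function(sub) {
    n <- nrow(sub)
    sub$start <- NA_real_
    sub$end <- NA_real_
    for (i in seq_len(n)) {
      others_end <- sub$basal_end[-i]
      others_start <- sub$basal_start[-i]
      left_wall <- others_end[others_end <= sub$basal_start[i]]
      right_wall <- others_start[others_start >= sub$basal_end[i]]
      left <- max(sub$tss[i] - max_extension,
                  if (length(left_wall)) max(left_wall) else -Inf, 0)
      right <- min(sub$tss[i] + max_extension,
                   if (length(right_wall)) min(right_wall) else Inf)
      sub$start[i] <- min(left, sub$basal_start[i])
      sub$end[i] <- max(right, sub$basal_end[i])
    }
    sub
  })
  out <- do.call(rbind, pieces)
  out <- out[match(genes$id, out$id),
             c("id", "chrom", "basal_start", "basal_end", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Link DMRs to genes through regulatory domains
#'
#' A DMR is linked to every gene whose extended regulatory domain it
#' overlaps by at least 1 bp. DMRs overlapping no domain get zero links.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`).
#' @param domains output of [build_regulatory_domains()].
#' @return data.frame of links: `dmr` (row index into `dmrs`), `id`
#'   (gene id).
#' @export
link_dmrs_to_genes <- function(dmrs, domains) {
  if (nrow(dmrs) == 0L || nrow(domains) == 0L) {
    return(data.frame(dmr = integer(), id = character()))
  }
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(dmrs$chrom,
                           IRanges::IRanges(dmrs$start + 1L, dmrs$end)),
    GenomicRanges::GRanges(domains$chrom,
                           IRanges::IRanges(domains$start + 1L,
                                            domains$end))
  )
  data.frame(dmr = S4Vectors::queryHits(hits),
             id = domains$id[S4Vectors::subjectHits(hits)])
}

#' Classify per-gene expression changes between two stages
#'
#' A gene is called changed when its fold change (larger FPKM over
#' smaller) exceeds `fold_threshold` AND the absolute FPKM difference
#' exceeds `delta_threshold`, jointly. With a zero FPKM in one stage the
#' fold change is undefined and the fold criterion is treated as
#' satisfied, so the call reduces to the delta criterion. Swapping the
#' stages flips up and down calls and preserves "none".
#'
#' @param expr expression data.frame (`id` plus stage columns).
#' @param stage_a,stage_b stage column names (change is B relative to
#'   A).
#' @param fold_threshold minimum fold change (default 2.0, exclusive).
#' @param delta_threshold minimum |FPKM difference| (default 5.0,
#'   exclusive).
#' @return data.frame: `id`, `fpkm_a`, `fpkm_b`, `fold_change` (`Inf`
#'   for zero denominators, `NA` when both are 0), `delta_fpkm`, `call`
#'   in `{"up", "down", "none"}`.
#' @export
classify_expression_change <- function(expr, stage_a, stage_b,
                                       fold_threshold = 2.0,
                                       delta_threshold = 5.0) {
  a <- expr[[stage_a]]
  b <- expr[[stage_b]]
  if (is.null(a) || is.null(b)) stop("stage column missing")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  fold <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, NA_real_))
  delta <- abs(b - a)
  fold_ok <- ifelse(lo > 0, fold > fold_threshold, TRUE)
  changed <- fold_ok & delta > delta_threshold
  data.frame(
    id = expr$id, fpkm_a = a, fpkm_b = b, fold_change = fold,
    delta_fpkm = delta,
    call = ifelse(changed, ifelse(b > a, "up", "down"), "none")
  )
}

#' Chi-squared enrichment of expression change among linked genes
#'
#' Pearson chi-squared test (df = 1, no continuity correction) on the
#' 2x2 table of linked/non-linked by changed/unchanged genes, asking
#' whether DMR-linked genes change expression more often than the
#' overall gene set.
#'
#' @param linked_changed,linked_total changed and total counts among
#'   DMR-linked genes.
#' @param all_changed,all_total changed and total counts in the entire
#'   gene set (including the linked genes).
#' @return list with `statistic`, `p_value`, `table` (the 2x2 counts),
#'   and `expected`.
#' @export
enrichment_chisq <- function(linked_changed, linked_total, all_changed,
                             all_total) {
  other_changed <- all_changed - linked_changed
  other_total <- all_total - linked_total
  tab <- matrix(c(linked_changed, linked_total - linked_changed,
                  other_changed, other_total - other_changed),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("linked", "other"),
                                c("changed", "unchanged")))
  if (any(tab < 0)) stop("inconsistent counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in the 2x2 table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) warning("expected cell count below 1")
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       table = tab, expected = expected)
}
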