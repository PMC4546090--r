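# Shared fixture builders: everything is generated in code at test time.

# Quick call-table builder with sensible defaults.
make_calls <- function(pos, n_meth, n_total, chrom = "chr1", strand = "*",
                       context = "CG", ...) {
  cytosine_calls(data.frame(chrom = rep_len(chrom, length(pos)),
                            pos = as.integer(pos),
                            strand = rep_len(strand, length(pos)),
                            context = rep_len(context, length(pos)),
                            n_meth = as.integer(n_meth),
                            n_total = as.integer(n_total)), ...)
}

# Pool replicates, strand-merge, coverage-filter: the standard prep.
prep_stage <- function(replicate_tables) {
  filter_by_coverage(merge_symmetric_cg(pool_replicates(replicate_tables)))
}

# Two-stage study config for DMR screens: one 5-Mb chromosome, planted
# DMRs with a 40-point true difference (0.85 vs 0.45) among otherwise
# identical 0.85-level methylomes, 2 replicates at 15x per strand.
two_stage_config <- function(seed, n_dmrs = 100L, chrom_len = 5e6) {
  sim_config(
    seed = seed, chrom_lengths = c(sim = chrom_len), ch_spacing = Inf,
    pmd = list(n_per_chrom = 0, length_range = c(1e6, 2e6), level = 0.45),
    dmr = list(n_per_archetype = n_dmrs, width = 800L, n_sites = 8L,
               archetypes = matrix(c(0.85, 0.45), 1L)),
    stages = c("A", "B"), ch_level = c(0, 0)
  )
}

# False-discovery proportion and sensitivity of called vs planted DMRs.
score_dmr_calls <- function(called, truth) {
  if (nrow(called) == 0L) {
    return(list(fdp = NA_real_, sensitivity = 0, n_called = 0L))
  }
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(called$chrom,
                           IRanges::IRanges(called$start + 1L, called$end)),
    GenomicRanges::GRanges(truth$chrom,
                           IRanges::IRanges(truth$start + 1L, truth$end))
  )
  fp <- nrow(called) - length(unique(S4Vectors::queryHits(hits)))
  list(fdp = fp / nrow(called),
       sensitivity = length(unique(S4Vectors::subjectHits(hits))) /
         nrow(truth),
       n_called = nrow(called))
}

# Run the two-stage screen end to end for one seed.
run_dmr_screen <- function(seed, ...) {
  sim <- simulate_methylome(two_stage_config(seed, ...))
  a <- prep_stage(sim$samples$A)
  b <- prep_stage(sim$samples$B)
  res <- find_dmrs(a, b)
  c(score_dmr_calls(res$dmrs, sim$truth$dmrs), list(dmrs = res$dmrs))
}

# Jaccard index between two interval sets on one chromosome (bp).
interval_jaccard <- function(a, b) {
  cov_bp <- function(x) sum(x$end - x$start)
  inter <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      inter <- inter +
        max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
    }
  }
  inter / (cov_bp(a) + cov_bp(b) - inter)
}
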