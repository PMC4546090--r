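# 5-hydroxymethylcytosine estimation from paired BS/oxBS call tables.
# Bisulfite reads 5mC + 5hmC as methylated; oxidative bisulfite reads
# only 5mC, so the 5hmC level is the BS minus oxBS difference.

#' Estimate 5hmC from paired BS and oxBS call tables
#'
#' Restricts to sites present with at least `min_coverage` reads in both
#' assays and subtracts the oxBS level from the BS level. Per-site
#' negative differences (sampling noise) are clamped to 0 with the raw
#' difference retained for diagnostics. The pooled estimate subtracts
#' pooled levels (unclamped sums) by default, which is unbiased; set
#' `clamp_pooled = TRUE` to pool the per-site clamped values instead.
#'
#' @param bs_calls,oxbs_calls strand-merged, filtered call tables of the
#'   same compartment.
#' @param min_coverage minimum coverage in each assay (default 6, the CG
#'   coverage filter).
#' @param clamp_pooled pool per-site clamped values instead of
#'   subtracting pooled levels (default FALSE).
#' @return list of class `hydroxy_profile`: `sites` (per-site
#'   `bs_level`, `oxbs_level` = true 5mC, `hmc_raw`, `hmc_level`),
#'   `pooled_bs`, `pooled_oxbs`, `pooled_hmc`, `n_sites`, and
#'   `pooled_hmc_cg` / `pooled_hmc_ch` restricted to CG / CH sites (the
#'   genome-wide 5hmC level is conventionally reported at CG sites).
#' @export
estimate_5hmc <- function(bs_calls, oxbs_calls, min_coverage = 6L,
                          clamp_pooled = FALSE) {
  bs <- data.table::as.data.table(bs_calls)
  ox <- data.table::as.data.table(oxbs_calls)
  sites <- merge(
    bs[n_total >= min_coverage,
       .(chrom, pos, context, m_bs = n_meth, t_bs = n_total)],
    ox[n_total >= min_coverage,
       .(chrom, pos, m_ox = n_meth, t_ox = n_total)],
    by = c("chrom", "pos")
  )
  if (nrow(sites) == 0L) {
    stop("no site covered >= ", min_coverage, "x in both assays")
  }
  data.table::setorder(sites, chrom, pos)
  bs_level <- sites$m_bs / sites$t_bs
  ox_level <- sites$m_ox / sites$t_ox
  raw <- bs_level - ox_level
  per_site <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         context = sites$context, bs_level = bs_level,
                         oxbs_level = ox_level, hmc_raw = raw,
                         hmc_level = pmax(0, raw))
  pooled_bs <- sum(sites$m_bs) / sum(sites$t_bs)
  pooled_ox <- sum(sites$m_ox) / sum(sites$t_ox)
  pooled_hmc <- if (clamp_pooled) mean(per_site$hmc_level)
                else max(0, pooled_bs - pooled_ox)
  ctx_pool <- function(mask) {
    if (!any(mask)) return(NA_real_)
    if (clamp_pooled) return(mean(per_site$hmc_level[mask]))
    max(0, sum(sites$m_bs[mask]) / sum(sites$t_bs[mask]) -
          sum(sites$m_ox[mask]) / sum(sites$t_ox[mask]))
  }
  is_cg <- sites$context == "CG"
  structure(list(sites = per_site, pooled_bs = pooled_bs,
                 pooled_oxbs = pooled_ox, pooled_hmc = pooled_hmc,
                 pooled_hmc_cg = ctx_pool(is_cg),
                 pooled_hmc_ch = ctx_pool(!is_cg),
                 n_sites = nrow(per_site)),
            class = "hydroxy_profile")
}

#' Modified-base density per 100 bp
#'
#' Expected number of modified bases per 100 bp of a compartment: the
#' sum of per-site modification levels divided by the compartment
#' length, times 100. Computed separately for 5mC (oxBS level) and 5hmC,
#' this distinguishes a dense, moderately modified compartment (e.g.,
#' satellite repeats) from a sparse, highly modified one.
#'
#' @param profile a `hydroxy_profile`.
#' @param region_length compartment length in bp.
#' @return list with `hmc_per_100bp` and `mc_per_100bp`.
#' @export
modified_base_density <- function(profile, region_length) {
  if (region_length <= 0) stop("region_length must be positive")
  list(
    hmc_per_100bp = sum(profile$sites$hmc_level) / region_length * 100,
    mc_per_100bp = sum(profile$sites$oxbs_level) / region_length * 100
  )
}

#' Split 5hmC mass by sequence context
#'
#' Fractions of the total 5hmC signal occurring at CG versus CH sites.
#' Per-context totals sum the raw (unclamped) per-site differences and
#' are floored at 0, so symmetric sampling noise at unhydroxylated
#' sites cancels instead of accumulating through per-site clamping.
#'
#' @param profile a `hydroxy_profile` whose sites include CH records.
#' @return list with `cg_fraction`, `ch_fraction`, and the per-context
#'   totals.
#' @export
hmc_context_split <- function(profile) {
  s <- profile$sites
  if (nrow(s) == 0L) stop("empty hydroxymethylation profile")
  is_cg <- s$context == "CG"
  tot_cg <- max(0, sum(s$hmc_raw[is_cg]))
  tot_ch <- max(0, sum(s$hmc_raw[!is_cg]))
  tot <- tot_cg + tot_ch
  if (tot == 0) {
    return(list(cg_fraction = NA_real_, ch_fraction = NA_real_,
                total_cg = 0, total_ch = 0))
  }
  list(cg_fraction = tot_cg / tot, ch_fraction = tot_ch / tot,
       total_cg = tot_cg, total_ch = tot_ch)
}
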