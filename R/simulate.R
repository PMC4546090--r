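# Synthetic WGBS / RNA-seq generator with exact planted truth.
#
# Emulates the statistical structure of stage-resolved germ-cell WGBS:
# a latent CG methylome with planted partially methylated domains,
# stage-specific DMRs drawn from six archetype trajectories, genome-wide
# CH methylation that is high in P0.5 prospermatogonia and lost after
# the resumption of mitosis, 5hmC at CG sites, a small bisulfite
# conversion-failure rate, an unmethylated lambda-like spike-in, and
# binomial (optionally beta-binomial) read counts per site. Everything
# is deterministic given (config, seed).

#' Default DMR archetype trajectories
#'
#' Six archetypes of stage-wise true CG levels (P0.5, Kit-, Kit+), as
#' fractions. Archetypes 1/2/5/6 follow the well-characterized patterns
#' (1: high, stable, then strong loss; 2: high with progressive loss;
#' 5: low with progressive gain; 6: low, stable, then gain); archetypes
#' 3 and 4 are approximations of the sparsely populated patterns (3
#' gains methylation on the Kit- to Kit+ transition). Rows are already
#' in the canonical order used by [cluster_trajectories()] (descending
#' start level), so planted archetype i is recovered as cluster i.
#'
#' @return 6 x 3 matrix of stage levels.
#' @export
dmr_archetypes <- function() {
  m <- matrix(c(
    0.95, 0.95, 0.25,   # 1: high, stable, large loss
    0.70, 0.25, 0.10,   # 2: high, loss, further loss
    0.60, 0.55, 0.95,   # 3: mid, stable, late gain (approximate)
    0.45, 0.80, 0.45,   # 4: mid, gain, loss (approximate)
    0.25, 0.65, 0.95,   # 5: low, gain, further gain
    0.05, 0.05, 0.60    # 6: low, stable, gain
  ), nrow = 6L, byrow = TRUE)
  dimnames(m) <- list(archetype = 1:6, stage = c("stage1", "stage2",
                                                 "stage3"))
  m
}

#' Simulation configuration
#'
#' Defaults describe the desk-scale study design: two 5-Mb chromosomes,
#' CpG dyads every ~100 bp, CH sites every ~40 bp, sequencing depth 15x
#' per strand, two replicates of three stages, one planted ~2-Mb PMD per
#' chromosome at level 0.45 against a 0.85 background, DMRs from the six
#' archetype trajectories, CH methylation 0.10 in the first stage and
#' 0.01 afterwards, 5hmC 0.014 at CG sites, and a 0.3% conversion
#' failure rate.
#'
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param cg_spacing mean distance between CpG dyads (bp).
#' @param ch_spacing mean distance between CH sites (bp); `Inf` disables
#'   CH sites.
#' @param background_cg background true CG level.
#' @param pmd list: `n_per_chrom`, `length_range` (bp), `level`; set
#'   `n_per_chrom = 0` for a PMD-free genome.
#' @param dmr list: `n_per_archetype`, `width` (bp), `n_sites` (CG sites
#'   per DMR), `archetypes` (matrix of stage levels, one row per
#'   archetype; defaults to [dmr_archetypes()], columns recycled to the
#'   number of stages).
#' @param stages stage labels, in developmental order.
#' @param ch_level per-stage true CH level (recycled).
#' @param hmc_level true 5hmC level at CG sites (oxBS pairing).
#' @param conversion_failure bisulfite conversion-failure rate.
#' @param depth mean per-strand read depth (Poisson).
#' @param overdispersion beta-binomial intra-site correlation in
#'   \[0, 1); 0 gives pure binomial counts.
#' @param replicates biological replicates per stage.
#' @param spike list: `n_sites`, `depth` of the unmethylated spike-in.
#' @param expression list: `n_genes`, `fpkm_pmd_meanlog`,
#'   `fpkm_meanlog`, `sdlog`, `p_change_linked`, `p_change_background`,
#'   `fold_range` for [simulate_expression()].
#' @return config list (class `sim_config`).
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(simA = 5e6, simB = 5e6),
                       cg_spacing = 100,
                       ch_spacing = 40,
                       background_cg = 0.85,
                       pmd = list(n_per_chrom = 1, length_range = c(1.5e6, 2.5e6),
                                  level = 0.45),
                       dmr = list(n_per_archetype = 25, width = 800,
                                  n_sites = 8, archetypes = dmr_archetypes()),
                       stages = c("P0.5", "KitNeg", "KitPos"),
                       ch_level = c(0.10, 0.01, 0.01),
                       hmc_level = 0.014,
                       conversion_failure = 0.003,
                       depth = 15,
                       overdispersion = 0,
                       replicates = 2L,
                       spike = list(n_sites = 10000L, depth = 20),
                       expression = list(n_genes = 300L,
                                         fpkm_pmd_meanlog = log(0.3),
                                         fpkm_meanlog = log(8),
                                         sdlog = 0.8,
                                         p_change_linked = 0.5,
                                         p_change_background = 0.05,
                                         fold_range = c(3, 6))) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(background_cg, pmd$level, ch_level, hmc_level,
             conversion_failure)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must be in [0, 1)")
  }
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              cg_spacing = cg_spacing, ch_spacing = ch_spacing,
              background_cg = background_cg, pmd = pmd, dmr = dmr,
              stages = stages,
              ch_level = rep_len(ch_level, length(stages)),
              hmc_level = hmc_level,
              conversion_failure = conversion_failure, depth = depth,
              overdispersion = overdispersion,
              replicates = as.integer(replicates), spike = spike,
              expression = expression)
  class(cfg) <- "sim_config"
  cfg
}

# Observed methylation probability under random conversion failure at
# unmethylated cytosines: the mixing model inverted by
# correct_nonconversion().
observed_prob <- function(true_p, failure) true_p + (1 - true_p) * failure

# Read counts: depth ~ Poisson(mean), meth ~ Binomial(depth, p), with an
# optional beta-binomial layer (site-level p jitter).
draw_counts <- function(n, mean_depth, p, overdispersion = 0) {
  depth <- stats::rpois(n, mean_depth)
  if (overdispersion > 0) {
    rho <- overdispersion
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    pj <- ifelse(p <= 0, 0, ifelse(p >= 1, 1, stats::rbeta(n, pmax(a, 1e-8),
                                                           pmax(b, 1e-8))))
    p <- pj
  }
  meth <- stats::rbinom(n, depth, p)
  list(depth = depth, meth = meth)
}

# Place m non-overlapping intervals of given widths uniformly on
# [0, chrom_len), avoiding `avoid` intervals; simple rejection sampler.
place_intervals <- function(m, widths, chrom_len, avoid = NULL,
                            max_tries = 2000L) {
  if (m > 0 && any(widths >= chrom_len)) {
    stop("interval width exceeds chromosome length")
  }
  placed <- if (is.null(avoid)) {
    data.frame(start = numeric(0), end = numeric(0))
  } else {
    avoid[, c("start", "end"), drop = FALSE]
  }
  out <- data.frame(start = numeric(0), end = numeric(0))
  for (i in seq_len(m)) {
    w <- widths[i]
    for (try in seq_len(max_tries)) {
      s <- floor(stats::runif(1, 0, chrom_len - w))
      if (!any(s < placed$end & s + w > placed$start)) {
        placed <- rbind(placed, data.frame(start = s, end = s + w))
        out <- rbind(out, data.frame(start = s, end = s + w))
        break
      }
      if (try == max_tries) stop("could not place interval; genome too full")
    }
  }
  out
}

# Build the latent site map: CG dyads and CH sites with per-stage true
# levels, plus planted PMD/DMR truth intervals.
build_truth <- function(config) {
  n_stages <- length(config$stages)
  arch <- config$dmr$archetypes
  if (is.null(arch)) arch <- dmr_archetypes()
  arch <- arch[, rep_len(seq_len(ncol(arch)), n_stages), drop = FALSE]
  pmds <- list(); dmrs <- list(); sites <- list()
  n_arch <- nrow(arch)
  for (cc in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[cc]]
    # PMDs
    n_pmd <- config$pmd$n_per_chrom
    pmd_cc <- if (n_pmd > 0) {
      widths <- floor(stats::runif(n_pmd, config$pmd$length_range[1],
                                   config$pmd$length_range[2]))
      iv <- place_intervals(n_pmd, widths, len)
      data.frame(chrom = cc, start = iv$start, end = iv$end,
                 level = config$pmd$level)
    } else {
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), level = numeric(0))
    }
    # DMRs (outside PMDs, non-overlapping)
    n_dmr_chrom <- config$dmr$n_per_archetype * n_arch
    dmr_cc <- if (n_dmr_chrom > 0) {
      iv <- place_intervals(n_dmr_chrom,
                            rep(config$dmr$width, n_dmr_chrom), len,
                            avoid = pmd_cc)
      data.frame(chrom = cc, start = iv$start, end = iv$end,
                 archetype = rep(seq_len(n_arch),
                                 each = config$dmr$n_per_archetype))
    } else {
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), archetype = integer(0))
    }
    # background CG dyads
    n_cg <- ceiling(len / config$cg_spacing * 1.3)
    gaps <- pmax(2, round(stats::rexp(n_cg, 1 / config$cg_spacing)))
    pos <- cumsum(gaps)
    pos <- pos[pos < len - 1]
    # drop background dyads inside DMRs; DMRs get dedicated sites
    if (nrow(dmr_cc)) {
      inside <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(dmr_cc))) {
        inside <- inside | (pos >= dmr_cc$start[i] & pos < dmr_cc$end[i])
      }
      pos <- pos[!inside]
    }
    lev <- matrix(config$background_cg, length(pos), n_stages)
    if (nrow(pmd_cc)) {
      for (i in seq_len(nrow(pmd_cc))) {
        in_pmd <- pos >= pmd_cc$start[i] & pos < pmd_cc$end[i]
        lev[in_pmd, ] <- pmd_cc$level[i]
      }
    }
    cg <- data.frame(chrom = cc, pos = as.integer(pos), context = "CG")
    cg_lev <- lev
    # dedicated DMR sites (evenly spaced within each DMR)
    if (nrow(dmr_cc)) {
      spacing <- floor(config$dmr$width / config$dmr$n_sites)
      dpos <- unlist(lapply(seq_len(nrow(dmr_cc)), function(i) {
        dmr_cc$start[i] + spacing %/% 2 +
          seq.int(0L, by = spacing, length.out = config$dmr$n_sites)
      }))
      dlev <- arch[rep(dmr_cc$archetype, each = config$dmr$n_sites), ,
                   drop = FALSE]
      cg <- rbind(cg, data.frame(chrom = cc, pos = as.integer(dpos),
                                 context = "CG"))
      cg_lev <- rbind(cg_lev, dlev)
    }
    ord <- order(cg$pos)
    cg <- cg[ord, ]; cg_lev <- cg_lev[ord, , drop = FALSE]
    sites[[cc]] <- list(cg = cg, cg_lev = cg_lev)
    pmds[[cc]] <- pmd_cc
    dmrs[[cc]] <- dmr_cc
  }
  pmds <- do.call(rbind, pmds)
  dmrs <- do.call(rbind, dmrs)
  rownames(pmds) <- rownames(dmrs) <- NULL
  if (nrow(dmrs)) {
    tl <- arch[dmrs$archetype, , drop = FALSE]
    colnames(tl) <- paste0("level_", config$stages)
    dmrs <- cbind(dmrs, as.data.frame(tl))
  }
  list(pmds = pmds, dmrs = dmrs, sites = sites, archetypes = arch)
}

# CH site map for one chromosome (single-strand cytosines).
build_ch_sites <- function(cc, len, ch_spacing) {
  if (!is.finite(ch_spacing)) {
    return(NULL)
  }
  n_ch <- ceiling(len / ch_spacing * 1.3)
  pos <- cumsum(pmax(1, round(stats::rexp(n_ch, 1 / ch_spacing))))
  pos <- pos[pos < len]
  n <- length(pos)
  data.frame(
    chrom = cc, pos = as.integer(pos),
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CHG", "CHH"), n, replace = TRUE,
                     prob = c(0.25, 0.75)),
    dinucleotide = sample(c("CA", "CT", "CC"), n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2))
  )
}

# Relative methylation propensity by CH dinucleotide (CA most
# methylated), normalized to mean 1 under the sampling probabilities.
ch_dinuc_factor <- c(CA = 1.6, CT = 0.6, CC = 0.4)

# Drop CH sites colliding with either cytosine of a CpG dyad.
drop_ch_collisions <- function(ch, cg) {
  if (is.null(ch) || nrow(ch) == 0L) return(ch)
  taken <- paste(rep(cg$chrom, 2L), c(cg$pos, cg$pos + 1L))
  ch[!paste(ch$chrom, ch$pos) %in% taken, , drop = FALSE]
}

emit_sample <- function(cg, cg_lev_stage, ch, ch_level_stage, config) {
  failure <- config$conversion_failure
  # CG dyads: one record per strand, each with its own depth
  p_obs <- observed_prob(cg_lev_stage, failure)
  plus <- draw_counts(nrow(cg), config$depth, p_obs,
                      config$overdispersion)
  minus <- draw_counts(nrow(cg), config$depth, p_obs,
                       config$overdispersion)
  cg_rec <- data.frame(
    chrom = rep(cg$chrom, 2L),
    pos = c(cg$pos, cg$pos + 1L),
    strand = rep(c("+", "-"), each = nrow(cg)),
    context = "CG",
    n_meth = c(plus$meth, minus$meth),
    n_total = c(plus$depth, minus$depth),
    dinucleotide = "CG"
  )
  recs <- cg_rec
  if (!is.null(ch) && nrow(ch)) {
    fac <- ch_dinuc_factor[ch$dinucleotide]
    fac <- fac / sum(ch_dinuc_factor * c(0.5, 0.3, 0.2))
    p_ch <- observed_prob(pmin(1, ch_level_stage * fac), failure)
    drawn <- draw_counts(nrow(ch), config$depth, p_ch,
                         config$overdispersion)
    ch_rec <- data.frame(chrom = ch$chrom, pos = ch$pos,
                         strand = ch$strand, context = ch$context,
                         n_meth = drawn$meth, n_total = drawn$depth,
                         dinucleotide = ch$dinucleotide)
    recs <- rbind(cg_rec, ch_rec)
  }
  recs <- recs[recs$n_total > 0, , drop = FALSE]
  recs <- recs[order(recs$chrom, recs$pos), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Simulate an unmethylated spike-in call table
#'
#' Every methylated call is a planted conversion failure.
#'
#' @param n_sites number of spike-in cytosines.
#' @param depth mean read depth (Poisson).
#' @param failure_rate true conversion-failure rate.
#' @return spike-in call table (compartment `"spike_in"`).
#' @export
simulate_spike_in <- function(n_sites, depth, failure_rate) {
  drawn <- draw_counts(n_sites, depth, failure_rate)
  df <- data.frame(chrom = "lambda", pos = seq_len(n_sites) * 10L,
                   strand = "+", context = "CHH",
                   n_meth = drawn$meth, n_total = drawn$depth)
  df <- df[df$n_total > 0, , drop = FALSE]
  cytosine_calls(df, assay = "BS", compartment = "spike_in")
}

#' Simulate a stage-resolved bisulfite methylome
#'
#' Generates per-stage, per-replicate BS call tables plus spike-in
#' tables and the complete planted truth. Per site, read depth is
#' Poisson and the methylated-read count binomial (beta-binomial when
#' `overdispersion > 0`) with success probability
#' `true + (1 - true) * failure`. CpG dyads are emitted on both strands
#' (to be recombined by [merge_symmetric_cg()]); CH sites on one strand.
#'
#' @param config a [sim_config()].
#' @return list: `samples[[stage]][[replicate]]` call tables,
#'   `spike[[stage]][[replicate]]` spike-in tables, and `truth` (planted
#'   PMDs, DMRs with archetypes and per-stage levels, conversion-failure
#'   rate, per-stage CH levels, seed).
#' @export
simulate_methylome <- function(config) {
  set.seed(config$seed)
  truth <- build_truth(config)
  ch_all <- lapply(names(config$chrom_lengths), function(cc) {
    build_ch_sites(cc, config$chrom_lengths[[cc]], config$ch_spacing)
  })
  ch_all <- if (all(vapply(ch_all, is.null, logical(1)))) NULL
            else do.call(rbind, ch_all)
  cg_all <- do.call(rbind, lapply(truth$sites, `[[`, "cg"))
  cg_lev_all <- do.call(rbind, lapply(truth$sites, `[[`, "cg_lev"))
  ch_all <- drop_ch_collisions(ch_all, cg_all)
  samples <- list(); spikes <- list()
  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    samples[[stage]] <- list(); spikes[[stage]] <- list()
    for (ri in seq_len(config$replicates)) {
      rec <- emit_sample(cg_all, cg_lev_all[, si], ch_all,
                         config$ch_level[si], config)
      samples[[stage]][[ri]] <- cytosine_calls(rec, assay = "BS",
                                               stage = stage,
                                               replicate = as.character(ri))
      spikes[[stage]][[ri]] <- simulate_spike_in(
        config$spike$n_sites, config$spike$depth,
        config$conversion_failure)
    }
  }
  list(samples = samples, spike = spikes,
       truth = list(pmds = truth$pmds, dmrs = truth$dmrs,
                    archetypes = truth$archetypes,
                    conversion_failure = config$conversion_failure,
                    ch_level = setNames(config$ch_level, config$stages),
                    hmc_level = config$hmc_level, seed = config$seed,
                    config = config))
}

#' Simulate a paired BS / oxBS experiment
#'
#' For the first stage of `config`: the true 5mC level per CG site
#' follows the methylome truth (background/PMD/DMR) and a constant true
#' 5hmC level (`config$hmc_level`) is added at every CG site. Bisulfite
#' reads both marks as methylated (observed p ~ 5mC + 5hmC); oxidative
#' bisulfite reads only 5mC. Both assays share the conversion-failure
#' mixing. CH sites carry `hmc_ch_level` 5hmC (default 0: almost all
#' 5hmC is at CG sites).
#'
#' @param config a [sim_config()].
#' @param hmc_ch_level true 5hmC level at CH sites (default 0).
#' @return list: `bs` and `oxbs` replicate lists of call tables, plus
#'   `truth` (`hmc_level`, `mc_sites` summary, seed).
#' @export
simulate_oxbs_pair <- function(config, hmc_ch_level = 0) {
  set.seed(config$seed)
  truth <- build_truth(config)
  cg_all <- do.call(rbind, lapply(truth$sites, `[[`, "cg"))
  mc <- do.call(rbind, lapply(truth$sites, `[[`, "cg_lev"))[, 1L]
  if (any(mc + config$hmc_level > 1)) stop("5mC + 5hmC exceeds 1")
  ch_all <- lapply(names(config$chrom_lengths), function(cc) {
    build_ch_sites(cc, config$chrom_lengths[[cc]], config$ch_spacing)
  })
  ch_all <- if (all(vapply(ch_all, is.null, logical(1)))) NULL
            else do.call(rbind, ch_all)
  ch_all <- drop_ch_collisions(ch_all, cg_all)
  emit_assay <- function(cg_p, ch_p) {
    cfg <- config
    lapply(seq_len(config$replicates), function(ri) {
      rec <- emit_sample(cg_all, cg_p, ch_all, ch_p, cfg)
      cytosine_calls(rec, assay = "BS", stage = config$stages[1L],
                     replicate = as.character(ri))
    })
  }
  ch_mc <- config$ch_level[1L]
  bs <- emit_assay(mc + config$hmc_level, ch_mc + hmc_ch_level)
  oxbs <- emit_assay(mc, ch_mc)
  list(bs = bs, oxbs = oxbs,
       truth = list(hmc_level = config$hmc_level,
                    hmc_ch_level = hmc_ch_level, mc_mean = mean(mc),
                    seed = config$seed))
}

#' Simulate planted DMR trajectory matrices
#'
#' Draws `n_per_archetype` trajectories per archetype and adds Gaussian
#' noise, for validating the clustering and k-selection machinery
#' against planted labels.
#'
#' @param seed integer seed.
#' @param n_per_archetype trajectories per archetype (default 100).
#' @param noise_sd noise standard deviation in percentage points
#'   (default 5).
#' @param archetypes stage-level matrix as in [dmr_archetypes()].
#' @return list: `matrix` (data.frame `l0`, `d1`, `d2`) and planted
#'   `labels`.
#' @export
simulate_trajectories <- function(seed, n_per_archetype = 100L,
                                  noise_sd = 5,
                                  archetypes = dmr_archetypes()) {
  set.seed(seed)
  lv <- archetypes[rep(seq_len(nrow(archetypes)),
                       each = n_per_archetype), , drop = FALSE] * 100
  lv <- lv + matrix(stats::rnorm(length(lv), 0, noise_sd), nrow(lv))
  lv <- pmin(pmax(lv, 0), 100)
  list(matrix = data.frame(l0 = lv[, 1L], d1 = lv[, 2L] - lv[, 1L],
                           d2 = lv[, 3L] - lv[, 2L]),
       labels = rep(seq_len(nrow(archetypes)), each = n_per_archetype))
}

#' Simulate gene models and stage-wise expression
#'
#' Places genes with TSSs inside and outside the planted PMDs, draws
#' FPKM from a low log-normal for PMD genes and a higher one for
#' non-PMD genes, and plants expression changes between consecutive
#' stages with elevated probability for genes whose regulatory domains
#' overlap a planted DMR. Planted changes multiply or divide FPKM by a
#' factor in `fold_range` starting from at least 5 FPKM, so they clear
#' the fold > 2 and delta > 5 thresholds by construction.
#'
#' @param config a [sim_config()].
#' @param truth truth component of [simulate_methylome()] output (needs
#'   `pmds` and `dmrs`).
#' @return list: `genes` (gene models with `pmd_gene` flag),
#'   `expression` (id + one FPKM column per stage), `truth_genes`
#'   (per-gene linked/changed flags per transition).
#' @export
simulate_expression <- function(config, truth) {
  set.seed(config$seed + 1L)
  ex <- config$expression
  n <- ex$n_genes
  chroms <- names(config$chrom_lengths)
  chrom <- sample(chroms, n, replace = TRUE)
  tss <- floor(stats::runif(n, 5000,
                            config$chrom_lengths[chrom] - 5000))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  width <- pmax(2000, round(stats::rlnorm(n, log(10000), 0.5)))
  start <- ifelse(strand == "+", tss, pmax(0, tss - width))
  end <- ifelse(strand == "+", tss + width, tss)
  genes <- gene_models(data.frame(
    id = sprintf("G%04d", seq_len(n)), chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand))
  genes$pmd_gene <- assign_pmd_genes(genes, truth$pmds) == "PMD"
  domains <- build_regulatory_domains(genes)
  links <- link_dmrs_to_genes(truth$dmrs, domains)
  linked <- genes$id %in% links$id
  base <- ifelse(genes$pmd_gene,
                 stats::rlnorm(n, ex$fpkm_pmd_meanlog, ex$sdlog),
                 stats::rlnorm(n, ex$fpkm_meanlog, ex$sdlog))
  n_stages <- length(config$stages)
  fpkm <- matrix(base, n, n_stages)
  p_change <- ifelse(linked, ex$p_change_linked, ex$p_change_background)
  changed <- matrix(FALSE, n, n_stages - 1L)
  for (tr in seq_len(n_stages - 1L)) {
    flip <- stats::runif(n) < p_change & !genes$pmd_gene
    fac <- stats::runif(n, ex$fold_range[1], ex$fold_range[2])
    want_up <- stats::runif(n) < 0.5
    # a "down" flip from a low baseline cannot clear the delta
    # criterion; such flips are planted upward instead
    can_down <- fpkm[, tr] * (1 - 1 / fac) > 5
    up <- want_up | !can_down
    new_val <- ifelse(up, pmax(fpkm[, tr], 5) * fac, fpkm[, tr] / fac)
    fpkm[, tr + 1L] <- ifelse(flip, new_val, fpkm[, tr])
    changed[, tr] <- flip
  }
  expr <- data.frame(id = genes$id)
  for (si in seq_len(n_stages)) expr[[config$stages[si]]] <- fpkm[, si]
  truth_genes <- data.frame(id = genes$id, pmd_gene = genes$pmd_gene,
                            linked = linked)
  for (tr in seq_len(n_stages - 1L)) {
    truth_genes[[paste0("changed_", tr)]] <- changed[, tr]
  }
  list(genes = genes, expression = expr, truth_genes = truth_genes)
}
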