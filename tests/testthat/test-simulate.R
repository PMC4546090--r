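# The synthetic-data generator: determinism, marginal fidelity, and
# truth-table consistency.

small_cfg <- function(seed, ...) {
  sim_config(seed = seed, chrom_lengths = c(sim = 5e5), ch_spacing = 100,
             pmd = list(n_per_chrom = 1, length_range = c(1e5, 1.5e5),
                        level = 0.45),
             dmr = list(n_per_archetype = 2, width = 800, n_sites = 8,
                        archetypes = dmr_archetypes()),
             ...)
}

test_that("identical config and seed reproduce bit-identical output", {
  s1 <- simulate_methylome(small_cfg(7))
  s2 <- simulate_methylome(small_cfg(7))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$spike, s2$spike)
  expect_identical(s1$truth$pmds, s2$truth$pmds)
  expect_identical(s1$truth$dmrs, s2$truth$dmrs)
  s3 <- simulate_methylome(small_cfg(8))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("degenerate probabilities produce degenerate reads", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(sim = 1e5),
                    ch_spacing = Inf, background_cg = 1,
                    conversion_failure = 0,
                    pmd = list(n_per_chrom = 0,
                               length_range = c(1e4, 2e4), level = 0.45),
                    dmr = list(n_per_archetype = 0, width = 800,
                               n_sites = 8,
                               archetypes = dmr_archetypes()),
                    stages = "S", ch_level = 0, replicates = 1L)
  sim <- simulate_methylome(cfg)
  calls <- sim$samples$S[[1]]
  expect_true(all(calls$n_meth == calls$n_total))
  expect_true(all(sim$spike$S[[1]]$n_meth == 0))
})

test_that("emitted global CG level matches the configured mixture", {
  cfg <- small_cfg(11)
  sim <- simulate_methylome(cfg)
  calls <- prep_stage(sim$samples[["P0.5"]])
  pmd_bp <- sum(sim$truth$pmds$end - sim$truth$pmds$start)
  dmr_bp <- sum(sim$truth$dmrs$end - sim$truth$dmrs$start)
  pmd_frac <- pmd_bp / 5e5
  expected <- 0.85 * (1 - pmd_frac) + 0.45 * pmd_frac
  got <- methylation_level(calls, context = "CG")
  # DMR sites perturb the mixture by at most their genome share
  expect_lt(abs(got - expected), 0.01 + dmr_bp / 5e5)
})

test_that("spike-in emission matches the planted failure rate", {
  cfg <- small_cfg(13)
  sim <- simulate_methylome(cfg)
  est <- estimate_nonconversion(sim$spike[["P0.5"]][[1]])
  se <- sqrt(0.003 * 0.997 / (10000 * 20))
  expect_lt(abs(est - 0.003), 4 * se)
})

test_that("planted DMR truth carries archetype stage levels", {
  sim <- simulate_methylome(small_cfg(17))
  truth <- sim$truth$dmrs
  expect_equal(nrow(truth), 2 * 6 * 1)  # 2 per archetype, 1 chromosome
  expect_true(all(truth$end - truth$start == 800))
  arch <- dmr_archetypes()
  expect_equal(truth$`level_P0.5`, arch[truth$archetype, 1],
               ignore_attr = TRUE)
  # planted truth is recoverable from emitted reads: measured level in
  # each DMR tracks the archetype level
  calls <- prep_stage(sim$samples[["KitPos"]])
  lv <- vapply(seq_len(nrow(truth)), function(i) {
    methylation_level(calls, region = truth[i, ], context = "CG")
  }, numeric(1))
  expect_lt(max(abs(lv - arch[truth$archetype, 3])), 0.2)
})

test_that("paired BS/oxBS expectations reflect 5mC plus 5hmC", {
  cfg <- sim_config(seed = 19, chrom_lengths = c(sim = 4e5),
                    ch_spacing = Inf, background_cg = 0.8,
                    hmc_level = 0.1, conversion_failure = 0,
                    pmd = list(n_per_chrom = 0,
                               length_range = c(1e5, 2e5), level = 0.45),
                    dmr = list(n_per_archetype = 0, width = 800,
                               n_sites = 8,
                               archetypes = dmr_archetypes()),
                    stages = "S", ch_level = 0)
  pair <- simulate_oxbs_pair(cfg)
  bs <- prep_stage(pair$bs)
  ox <- prep_stage(pair$oxbs)
  expect_lt(abs(methylation_level(bs) - 0.9), 0.005)
  expect_lt(abs(methylation_level(ox) - 0.8), 0.005)
  # zero 5hmC: expected BS - oxBS difference vanishes
  cfg0 <- sim_config(seed = 20, chrom_lengths = c(sim = 4e5),
                     ch_spacing = Inf, hmc_level = 0,
                     pmd = list(n_per_chrom = 0,
                                length_range = c(1e5, 2e5), level = 0.45),
                     dmr = list(n_per_archetype = 0, width = 800,
                                n_sites = 8,
                                archetypes = dmr_archetypes()),
                     stages = "S", ch_level = 0)
  pair0 <- simulate_oxbs_pair(cfg0)
  prof0 <- estimate_5hmc(prep_stage(pair0$bs), prep_stage(pair0$oxbs))
  expect_lt(abs(prof0$pooled_bs - prof0$pooled_oxbs), 0.005)
})

test_that("oxBS simulation rejects impossible 5mC + 5hmC", {
  cfg <- small_cfg(21)
  cfg$background_cg <- 0.995
  cfg$hmc_level <- 0.05
  expect_error(simulate_oxbs_pair(cfg), "exceeds 1")
})

test_that("planted expression changes match the threshold classifier", {
  cfg <- small_cfg(23)
  sim <- simulate_methylome(cfg)
  ge <- simulate_expression(cfg, sim$truth)
  calls <- classify_expression_change(ge$expression, "P0.5", "KitNeg")
  planted <- ge$truth_genes$changed_1
  expect_equal(calls$call != "none", planted)
  # with no planted changes nothing is called
  cfg0 <- small_cfg(24, expression = list(
    n_genes = 200L, fpkm_pmd_meanlog = log(0.3), fpkm_meanlog = log(8),
    sdlog = 0.8, p_change_linked = 0, p_change_background = 0,
    fold_range = c(3, 6)))
  sim0 <- simulate_methylome(cfg0)
  ge0 <- simulate_expression(cfg0, sim0$truth)
  calls0 <- classify_expression_change(ge0$expression, "P0.5", "KitNeg")
  expect_true(all(calls0$call == "none"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seed = 1, background_cg = 1.2), "probabilities")
  expect_error(sim_config(seed = 1, overdispersion = 1), "overdispersion")
  expect_error(sim_config(), "seed")
  bad <- small_cfg(1)
  bad$pmd$length_range <- c(6e5, 7e5)  # wider than the chromosome
  expect_error(simulate_methylome(bad), "width exceeds")
})
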