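# Sliding-window DMR calling: enumeration, Welch testing, BH
# correction, thresholding and merging.

# Build a two-stage pair of merged CG tables with given per-site counts.
make_pair <- function(pos, meth_a, tot_a, meth_b, tot_b, chrom = "chr1") {
  list(a = make_calls(pos, meth_a, tot_a, chrom = chrom),
       b = make_calls(pos, meth_b, tot_b, chrom = chrom))
}

test_that("window enumeration enforces the site and coverage rules", {
  # 20 sites every 100 bp at 20x: windows with 5 full sites start at
  # 0, 100, ..., 1500
  pos <- seq(0L, 1900L, by = 100L)
  pr <- make_pair(pos, 10L, 20L, 10L, 20L)
  cand <- enumerate_dmr_windows(pr$a, pr$b)
  expect_equal(nrow(cand), 16L)
  expect_equal(cand$start, seq(0L, 1500L, by = 100L))
  # only 4 qualifying sites -> no window
  pr4 <- make_pair(pos[1:4], 10L, 20L, 10L, 20L)
  expect_equal(nrow(enumerate_dmr_windows(pr4$a, pr4$b)), 0L)
  # 5 sites but one at 9x in one stage -> excluded there
  pr9 <- make_pair(pos[1:5], rep(5L, 5), c(20L, 20L, 20L, 20L, 9L),
                   rep(5L, 5), rep(20L, 5))
  expect_equal(nrow(enumerate_dmr_windows(pr9$a, pr9$b)), 0L)
})

test_that("the Welch test matches stats::t.test to machine precision", {
  a <- c(0.9, 0.8, 1.0, 0.85, 0.95)
  b <- c(0.4, 0.5, 0.45, 0.55, 0.35)
  res <- welch_site_test(a, b)
  oracle <- t.test(b, a, var.equal = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  expect_gt(abs(res$statistic), 8)  # clearly separated groups
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- runif(sample(5:12, 1))
      y <- runif(sample(5:12, 1))
      got <- welch_site_test(x, y)
      want <- t.test(y, x, var.equal = FALSE)
      expect_equal(got$statistic, unname(want$statistic),
                   tolerance = 1e-12)
      expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    }
  })
})

test_that("degenerate variance cases follow the explicit rule", {
  same <- rep(0.8, 6)
  expect_equal(welch_site_test(same, same)$p_value, 1)
  expect_equal(welch_site_test(same, same)$delta, 0)
  expect_equal(welch_site_test(rep(0.9, 5), rep(0.4, 5))$p_value, 0)
  # large variance swamps a 20-point delta
  noisy <- welch_site_test(c(0.99, 0.01, 0.99, 0.01, 0.99),
                           c(0.01, 0.99, 0.01, 0.99, 0.01))
  expect_gt(noisy$p_value, 0.2)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
    q[order(o)]
  }
  expect_equal(adjust_bh(c(0.001, 0.01, 0.02, 0.5)),
               c(0.004, 0.02, 0.02666666666666667, 0.5),
               tolerance = 1e-12)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.3), 0.3)
  withr::with_seed(77, {
    for (i in 1:200) {
      p <- runif(sample(1:100, 1))^sample(1:3, 1)
      q <- adjust_bh(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_equal(order(q[order(p)]), seq_along(p))  # order-preserving
    }
  })
})

test_that("significant windows merge into direction-stratified runs", {
  base <- data.frame(chrom = "chr1", n_sites = 5L, level_a = 0.9,
                     level_b = 0.4, delta = -50, mean_a = 0.9,
                     mean_b = 0.4, var_a = 0.001, var_b = 0.001,
                     statistic = -10, df = 8, p_value = 1e-6,
                     q_value = 1e-4)
  wins <- do.call(rbind, lapply(c(1000L, 1100L, 1400L), function(s) {
    transform(base, start = s, end = s + 500L)
  }))
  dmrs <- call_dmrs(wins)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(c(dmrs$start, dmrs$end), c(1000L, 1900L))
  expect_equal(dmrs$direction, "loss")
  # one isolated window -> minimal 500-bp DMR
  one <- call_dmrs(transform(base, start = 5000L, end = 5500L))
  expect_equal(one$end - one$start, 500L)
  # overlapping gain and loss windows stay separate DMRs
  gain <- transform(base, start = 1200L, end = 1700L, delta = 50,
                    level_a = 0.4, level_b = 0.9, mean_a = 0.4,
                    mean_b = 0.9, statistic = 10)
  both <- call_dmrs(rbind(wins, gain))
  expect_equal(nrow(both), 2L)
  expect_setequal(both$direction, c("gain", "loss"))
})

test_that("thresholds are joint and exclusive", {
  w <- data.frame(chrom = "chr1", start = 0L, end = 500L, n_sites = 5L,
                  level_a = 0.5, level_b = 0.9, delta = 40,
                  mean_a = 0.5, mean_b = 0.9, var_a = 0.01,
                  var_b = 0.01, statistic = 5, df = 8,
                  p_value = 0.001, q_value = 0.01)
  expect_equal(nrow(call_dmrs(w)), 1L)
  expect_equal(nrow(call_dmrs(transform(w, delta = 30))), 0L)
  expect_equal(nrow(call_dmrs(transform(w, p_value = 0.02))), 0L)
  expect_equal(nrow(call_dmrs(transform(w, q_value = 0.05))), 0L)
})

test_that("planted DMRs are recovered with high sensitivity and few false calls", {
  res <- run_dmr_screen(101)
  expect_gte(res$sensitivity, 0.8)
  expect_lte(res$fdp, 0.05)
  # structural invariants of merged DMRs
  len <- res$dmrs$end - res$dmrs$start
  expect_true(all(len >= 500L))
  expect_true(all((len - 500L) %% 100L == 0L))
})

test_that("a null two-stage comparison yields no DMRs", {
  sim <- simulate_methylome(two_stage_config(202, n_dmrs = 0L,
                                             chrom_len = 2e6))
  res <- find_dmrs(prep_stage(sim$samples$A), prep_stage(sim$samples$B))
  expect_equal(nrow(res$dmrs), 0L)
})

test_that("DMR locations are classified with promoter priority", {
  genes <- gene_models(data.frame(
    id = "g1", chrom = "chr1", start = 10000L, end = 30000L,
    strand = "+"))
  dmrs <- data.frame(chrom = "chr1",
                     start = c(8500L, 9900L, 15000L, 50000L),
                     end = c(9000L, 11000L, 15500L, 50500L))
  expect_equal(classify_dmr_location(dmrs, genes),
               c("promoter", "promoter", "intron", "intergenic"))
  # exon annotation upgrades body overlaps, promoter still wins
  exons <- data.frame(chrom = "chr1", start = 15000L, end = 16000L)
  expect_equal(classify_dmr_location(dmrs, genes, exons)[2:3],
               c("promoter", "exon"))
  expect_equal(nrow(dmr_promoter_overlap(dmrs, genes)), 2L)
  empty <- classify_dmr_location(dmrs, genes[0, ])
  expect_true(all(empty == "intergenic"))
})
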