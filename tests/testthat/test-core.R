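# Strand merging, coverage filtering, conversion correction, and
# methylation levels.

test_that("symmetric CG dyads are combined and CH passes through", {
  calls <- cytosine_calls(data.frame(
    chrom = "chr1", pos = c(1000L, 1001L, 2000L, 3000L),
    strand = c("+", "-", "+", "-"),
    context = c("CG", "CG", "CG", "CHH"),
    n_meth = c(3L, 2L, 4L, 1L), n_total = c(5L, 5L, 6L, 4L)))
  merged <- merge_symmetric_cg(calls)
  dyad <- merged[merged$pos == 1000L, ]
  expect_equal(dyad$n_meth, 5L)
  expect_equal(dyad$n_total, 10L)
  expect_equal(dyad$strand, "*")
  lone <- merged[merged$pos == 2000L, ]   # unpaired CG kept as-is
  expect_equal(lone$n_total, 6L)
  chh <- merged[merged$context == "CHH", ]
  expect_equal(chh$pos, 3000L)
  expect_equal(chh$strand, "-")
})

test_that("coverage filter applies context thresholds and is idempotent", {
  calls <- cytosine_calls(data.frame(
    chrom = "chr1", pos = c(0L, 10L, 20L, 30L, 40L),
    strand = "*",
    context = c("CG", "CG", "CHH", "CHH", "CG"),
    n_meth = c(0L, 0L, 0L, 0L, 50L),
    n_total = c(5L, 6L, 4L, 3L, 101L)))
  kept <- filter_by_coverage(calls)
  expect_equal(kept$pos, c(10L, 20L))  # CG@5 out, CG@101 out, CHH@3 out
  expect_equal(filter_by_coverage(kept)[, 1:6], kept[, 1:6],
               ignore_attr = TRUE)
})

test_that("nonconversion rate is the pooled spike-in methylation", {
  spike <- make_calls(pos = seq_len(10) * 10, n_meth = c(5, rep(0, 9)),
                      n_total = rep(100, 10), chrom = "lambda",
                      strand = "+", context = "CHH",
                      compartment = "spike_in")
  expect_equal(estimate_nonconversion(spike), 0.005)
  spike$n_meth <- 0L
  expect_equal(estimate_nonconversion(spike), 0)
  expect_error(estimate_nonconversion(spike[0, ]), "empty")
})

test_that("simulated spike-in recovers the planted failure rate", {
  spike <- withr::with_seed(42, simulate_spike_in(10000L, 20, 0.003))
  est <- estimate_nonconversion(spike)
  se <- sqrt(0.003 * 0.997 / sum(spike$n_total))
  expect_lt(abs(est - 0.003), 4 * se)
})

test_that("nonconversion correction inverts the mixing model exactly", {
  # frozen oracle value: (0.10 - 0.005) / (1 - 0.005)
  expect_equal(correct_nonconversion(0.10, 0.005), 0.0954773869346734)
  expect_equal(correct_nonconversion(0.005, 0.005), 0)
  expect_equal(correct_nonconversion(0.3, 0), 0.3)
  expect_error(correct_nonconversion(0.5, 1), "rate")
  grid <- expand.grid(t = seq(0, 1, by = 0.05), r = seq(0, 0.2, by = 0.02))
  observed <- grid$t + (1 - grid$t) * grid$r
  expect_equal(correct_nonconversion(observed, grid$r), grid$t,
               tolerance = 1e-12)
  expect_true(all(correct_nonconversion(observed, grid$r) <= observed))
})

test_that("methylation level is read-weighted, not a site mean", {
  calls <- make_calls(pos = c(0L, 100L), n_meth = c(3L, 10L),
                      n_total = c(4L, 100L))
  expect_equal(methylation_level(calls), 13 / 104)
  expect_equal(methylation_level(calls[1, ]), 0.75)
  expect_true(is.na(methylation_level(
    calls, region = list(chrom = "chr1", start = 500L, end = 600L))))
})

test_that("pooled level of a union lies between the parts", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- 30L
      tot <- sample(6:60, 2 * n, TRUE)
      calls <- make_calls(pos = seq_len(2 * n) * 10, n_total = tot,
                          n_meth = rbinom(2 * n, tot, runif(1)))
      lv_all <- methylation_level(calls)
      lv1 <- methylation_level(calls[seq_len(n), ])
      lv2 <- methylation_level(calls[n + seq_len(n), ])
      expect_gte(lv_all, min(lv1, lv2))
      expect_lte(lv_all, max(lv1, lv2))
    }
  })
})

test_that("context breakdown partitions all cytosines", {
  calls <- cytosine_calls(data.frame(
    chrom = "chr1", pos = c(0L, 10L, 20L), strand = "*",
    context = c("CG", "CHH", "CHG"), n_meth = c(0L, 0L, 0L),
    n_total = c(10L, 10L, 10L)))
  cb <- context_breakdown(calls, 0)
  expect_equal(c(cb$meth_cg, cb$meth_ch, cb$unmeth), c(0, 0, 1))
  cg_only <- calls[1, ]
  cg_only$n_meth <- 5L
  cb2 <- context_breakdown(cg_only, 0)
  expect_equal(cb2$meth_ch, 0)
  expect_equal(cb2$meth_cg + cb2$meth_ch + cb2$unmeth, 1)
})

test_that("window levels pool reads and respect the site minimum", {
  calls <- make_calls(pos = c(100L, 200L, 15000L),
                      n_meth = c(3L, 5L, 2L), n_total = c(4L, 6L, 8L))
  track <- window_levels(calls, size = 10000L,
                         chrom_lengths = c(chr1 = 100000L))
  expect_equal(nrow(track), 10L)          # tiling count
  expect_equal(track$level[1], 0.8)       # (3+5)/(4+6)
  expect_true(is.na(track$level[3]))      # empty window
  expect_equal(track$level[2], 0.25)
  expect_error(window_levels(calls, size = 100L, step = 200L), "step")
})

test_that("sliding windows share sites across overlapping starts", {
  calls <- make_calls(pos = c(50L, 450L), n_meth = c(1L, 3L),
                      n_total = c(2L, 4L))
  track <- window_levels(calls, size = 500L, step = 100L,
                         chrom_lengths = c(chr1 = 1000L))
  w0 <- track[track$start == 0, ]
  expect_equal(w0$n_sites, 2L)
  w100 <- track[track$start == 100, ]
  expect_equal(w100$n_sites, 1L)  # only pos 450
  expect_equal(w100$level, 0.75)
})

test_that("track correlation handles identity, complement, and nulls", {
  withr::with_seed(31, {
    lv <- runif(1000)
    tr <- data.frame(chrom = "chr1", start = seq_len(1000) * 10L,
                     level = lv)
    expect_equal(correlate_windows(tr, tr), 1.0)
    comp <- tr; comp$level <- 1 - lv
    expect_equal(correlate_windows(tr, comp), -1.0)
    indep <- tr; indep$level <- runif(1000)
    expect_lt(abs(correlate_windows(tr, indep)), 0.1)
    expect_lt(abs(correlate_windows(tr, indep, method = "spearman")), 0.1)
    expect_true(is.na(correlate_windows(tr[1:2, ], tr[1:2, ])))
  })
})
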