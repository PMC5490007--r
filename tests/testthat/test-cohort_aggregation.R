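test_that("binned log2 ratios follow the length-weighted mean", {
  uniform <- seg_df("S", "chr1", 0, 4e6, 1, 1)
  b <- bin_log_ratio(uniform, 2, 4e6)
  expect_equal(b$log2_ratio, rep(0, 4))

  amp <- rbind(seg_df("S", "chr1", 0, 1e6, 7, 1),
               seg_df("S", "chr1", 1e6, 4e6, 1, 1))
  b <- bin_log_ratio(amp, 2, 4e6)
  expect_equal(b$log2_ratio[1], 2)  # log2(8 / 2)

  mixed <- rbind(seg_df("S", "chr1", 0, 5e5, 1, 1),
                 seg_df("S", "chr1", 5e5, 1e6, 3, 1))
  b <- bin_log_ratio(mixed, 2, 1e6)
  expect_equal(b$log2_ratio, log2(3 / 2))

  # zero-CN bins are clamped at the floor
  zero <- seg_df("S", "chr1", 0, 1e6, 0, 0)
  b <- bin_log_ratio(zero, 2, 1e6)
  expect_equal(b$log2_ratio, log2(0.5 / 2))

  # gaps are imputed at ploidy
  gappy <- seg_df("S", "chr1", 0, 5e5, 3, 1)
  b <- bin_log_ratio(gappy, 2, 1e6)
  expect_equal(b$log2_ratio, log2(3 / 2))
})

test_that("aggregation reports mean and interpolated quartiles per bin", {
  m <- matrix(c(0, 0, 0, 2), nrow = 1)
  agg <- aggregate_profile(m)
  expect_equal(agg$mean, 0.5)
  expect_equal(agg$q1, 0)      # frozen from quantile type-7 oracle
  expect_equal(agg$q3, 0.5)

  one <- matrix(c(0.2, -1, 3), ncol = 1)
  agg1 <- aggregate_profile(one)
  expect_equal(agg1$mean, one[, 1])
  expect_equal(agg1$q1, one[, 1])
  expect_equal(agg1$q3, one[, 1])

  two <- cbind(one, one)
  expect_equal(aggregate_profile(two)$mean, one[, 1])
})

test_that("aggregation is sample-order invariant and quartile-ordered", {
  set.seed(5)
  m <- matrix(rnorm(40 * 8), nrow = 40)
  agg <- aggregate_profile(m)
  perm <- aggregate_profile(m[, sample(ncol(m))])
  expect_equal(agg, perm)
  med <- apply(m, 1, median)
  expect_true(all(agg$q1 <= med + 1e-12 & med <= agg$q3 + 1e-12))
})

test_that("recurrent regions merge adjacent bins and respect the threshold", {
  mk <- function(sample, chrom, r0, r1) {
    data.frame(sample = sample, chrom = chrom,
               class = "chromothripsis_amplification", n_breakpoints = 20L,
               n_cn_states = 2L, amplified_segment_count = 2L,
               region_start = r0, region_end = r1, stringsAsFactors = FALSE)
  }
  lens <- c(chr5 = 50e6)
  prof <- rbind(mk(c("A", "B", "C", "D"), "chr5", 10e6, 14e6),
                mk(c("A", "B", "C"), "chr5", 30e6, 33e6))
  reg <- recurrent_ca_regions(prof, lens, min_samples = 3L)
  expect_equal(nrow(reg), 2L)  # two disjoint regions, not merged
  expect_equal(reg$start, c(10e6, 30e6))
  expect_equal(reg$end, c(14e6, 33e6))
  expect_equal(reg$n_samples_ca, c(4, 3))

  none <- recurrent_ca_regions(prof, lens, min_samples = 10L)
  expect_equal(nrow(none), 0L)
})

test_that("recurrent regions recover planted recurrence with target genes", {
  sim <- simulate_cohort(simulation_config(seed = 21L))
  prof <- profile_cohort(sim$segments, sim$breakpoints)
  reg <- recurrent_ca_regions(prof$chromosomes, sim$config$chrom_lengths,
                              min_samples = 3L, panel = osteo_panel())
  expect_setequal(unique(reg$chrom), c("chr5", "chr12", "chr17"))
})
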