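ct_chrom <- function(seed = 1L, class = "chromothripsis", ploidy = 2L,
                     thr = 5L) {
  set.seed(seed)
  cfg <- simulation_config(seed = seed)
  simulate_chromosome(class, "S1", "chr17", 81e6, ploidy,
                      window = c(40e6, 60e6), config = cfg,
                      amp_threshold = thr)
}

test_that("copy-number state counting ignores tiny segments", {
  cn_seq <- function(cn) {
    n <- length(cn)
    seg_df(rep("S", n), rep("chr1", n), (seq_len(n) - 1) * 1e6,
           seq_len(n) * 1e6, cn, rep(0L, n))
  }
  expect_equal(count_cn_states(cn_seq(c(2, 1, 2, 1, 2))), 2L)
  expect_equal(count_cn_states(cn_seq(2)), 1L)
  expect_equal(count_cn_states(cn_seq(c(2, 1, 2, 7, 2, 1))), 3L)
  with_tiny <- rbind(cn_seq(c(2, 1, 2)),
                     seg_df("S", "chr1", 3e6, 3e6 + 5e3, 9L, 0L))
  expect_equal(count_cn_states(with_tiny), 2L)
  expect_equal(count_cn_states(cn_seq(integer())), 0L)
})

test_that("quiet and chromothriptic chromosomes are recognised", {
  quiet <- detect_chromothripsis(seg_df("S1", "chr1", 0, 50e6, 1, 1),
                                 chromamp:::.empty_breakpoints())
  expect_equal(quiet$class, "none")
  expect_equal(quiet$n_breakpoints, 0L)

  sim <- ct_chrom(3L)
  prof <- detect_chromothripsis(sim$segments, sim$breakpoints)
  expect_equal(prof$class, "chromothripsis")
  expect_gte(prof$n_breakpoints, 10L)
  expect_lte(prof$n_cn_states, 3L)
  # total-CN values on the chromosome stay within n_states + flanking ploidy
  expect_lte(length(unique(sim$segments$total_cn)), 3L)
})

test_that("rearrangements confined to one chromosome class only it", {
  sim <- ct_chrom(4L)
  other <- seg_df("S1", "chr3", 0, 100e6, 1, 1)
  prof <- profile_cohort(rbind(sim$segments, other), sim$breakpoints)
  chr17 <- prof$chromosomes[prof$chromosomes$chrom == "chr17", ]
  chr3 <- prof$chromosomes[prof$chromosomes$chrom == "chr3", ]
  expect_equal(chr17$class, "chromothripsis")
  expect_equal(chr3$class, "none")
  expect_equal(prof$genomes$class, "chromothripsis")
})

test_that("amplification upgrade requires interleaved high-level segments", {
  dip <- list(class = "diploid", ploidy = 2L)
  # chromothriptic with max CN 3: stays chromothripsis
  sim <- ct_chrom(5L)
  seg3 <- sim$segments
  seg3$total_cn[seg3$total_cn == 2L][1] <- 3L
  p <- detect_chromothripsis_amplification(seg3, sim$breakpoints, dip)
  expect_equal(p$class, "chromothripsis")

  # interleave a CN-20 amplicon inside the cluster: upgraded
  ca <- ct_chrom(6L, class = "chromothripsis_amplification")
  p2 <- detect_chromothripsis_amplification(ca$segments, ca$breakpoints, dip)
  expect_equal(p2$class, "chromothripsis_amplification")
  expect_gte(p2$amplified_segment_count, 1L)

  # a focal amplicon on an otherwise quiet chromosome is not chromothripsis
  quiet_amp <- chromamp:::.splice_segment(
    seg_df("S1", "chr2", 0, 100e6, 1, 1), 50e6, 50.4e6, 19L, 1L)
  p3 <- detect_chromothripsis_amplification(
    quiet_amp, chromamp:::.empty_breakpoints(), dip)
  expect_equal(p3$class, "none")
})

test_that("genome classification applies precedence and the quiet budget", {
  mk <- function(class, n_bkpt) {
    data.frame(sample = "S", chrom = "chr1", class = class,
               n_breakpoints = n_bkpt, n_cn_states = 1L,
               amplified_segment_count = 0L, region_start = NA_real_,
               region_end = NA_real_, stringsAsFactors = FALSE)
  }
  expect_equal(classify_genome(mk("none", 0L))$class, "quiet")
  expect_equal(classify_genome(rbind(mk("chromothripsis_amplification", 30L),
                                     mk("chromothripsis", 20L)))$class,
               "chromothripsis_amplification")
  expect_equal(classify_genome(mk("none", 9L))$class,
               "rearranged_non_chromothriptic")
})

test_that("adding breakpoints never demotes a chromosome class", {
  rank <- c(none = 1L, chromothripsis = 2L, chromothripsis_amplification = 3L)
  dip <- list(class = "diploid", ploidy = 2L)
  for (seed in 1:4) {
    sim <- ct_chrom(seed, class = sample(c("chromothripsis",
                                           "chromothripsis_amplification"), 1))
    before <- detect_chromothripsis_amplification(sim$segments,
                                                  sim$breakpoints, dip)
    extra <- bp_df("S1", "chr17", round(runif(1, 41e6, 59e6)), "+",
                   "chr17", round(runif(1, 41e6, 59e6)), "-")
    after <- detect_chromothripsis_amplification(
      sim$segments, rbind(sim$breakpoints, extra[, names(sim$breakpoints)]),
      dip)
    expect_gte(rank[[after$class]], rank[[before$class]])
  }
})

test_that("profiles are deterministic in their inputs", {
  sim <- ct_chrom(9L, class = "chromothripsis_amplification")
  dip <- list(class = "diploid", ploidy = 2L)
  a <- detect_chromothripsis_amplification(sim$segments, sim$breakpoints, dip)
  b <- detect_chromothripsis_amplification(sim$segments, sim$breakpoints, dip)
  expect_identical(a, b)
})
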