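small_config <- function(seed = 1L, ...) {
  simulation_config(
    n_samples = 6L,
    class_counts = c(quiet = 1L, chromothripsis = 2L,
                     chromothripsis_amplification = 3L),
    seed = seed, ...)
}

test_that("quiet chromosomes are a single segment at ploidy", {
  sim <- simulate_chromosome("quiet", "S1", "chr1", 50e6, 2L)
  expect_equal(nrow(sim$segments), 1L)
  expect_equal(sim$segments$major_cn, 1L)
  expect_equal(sim$segments$minor_cn, 1L)
  expect_null(sim$breakpoints)
  tet <- simulate_chromosome("quiet", "S1", "chr1", 50e6, 4L)
  expect_equal(tet$segments$total_cn, 4L)
  expect_error(simulate_chromosome("odd", "S1", "chr1", 50e6, 2L),
               "unknown chromosome class")
})

test_that("chromothriptic chromosomes oscillate among few states", {
  set.seed(2)
  sim <- simulate_chromosome("chromothripsis", "S1", "chr17", 81e6, 2L,
                             window = c(40e6, 60e6))
  expect_lte(length(unique(sim$segments$total_cn)), 3L)
  expect_gte(nrow(sim$breakpoints) * 2L, 10L)
  validate_segments(sim$segments)
})

test_that("cohort simulation is deterministic and emits valid files", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  s1 <- simulate_cohort(small_config(11L), out_dir = d1)
  s2 <- simulate_cohort(small_config(11L), out_dir = d2)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$tpm, s2$tpm)
  for (f in c("segments.tsv", "breakpoints.bedpe", "mutations.tsv",
              "expression.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # emitted files pass the readers' validation and round-trip
  seg <- read_segments(file.path(d1, "segments.tsv"))
  expect_equal(nrow(seg), nrow(s1$segments))
  bp <- read_breakpoints(file.path(d1, "breakpoints.bedpe"))
  expect_equal(nrow(bp), nrow(s1$breakpoints))
  mut <- read_mutations(file.path(d1, "mutations.tsv"))
  expect_equal(nrow(mut), nrow(s1$mutations))
  tpm <- read_expression(file.path(d1, "expression.tsv"))
  expect_equal(dim(tpm), dim(s1$tpm))
})

test_that("an empty cohort still yields schema-valid files", {
  cfg <- simulation_config(
    n_samples = 0L,
    class_counts = c(quiet = 0L, chromothripsis = 0L,
                     chromothripsis_amplification = 0L))
  d <- tempfile()
  sim <- simulate_cohort(cfg, out_dir = d)
  expect_equal(nrow(sim$segments), 0L)
  expect_equal(nrow(read_segments(file.path(d, "segments.tsv"))), 0L)
  expect_equal(nrow(read_breakpoints(file.path(d, "breakpoints.bedpe"))), 0L)
})

test_that("planted disruptive breakpoints land inside the gene footprint", {
  cfg <- small_config(
    13L,
    planted_drivers = data.frame(sample = "S004", gene = "NF1",
                                 mechanism = "disruptive_breakpoint",
                                 stringsAsFactors = FALSE))
  sim <- simulate_cohort(cfg)
  nf1 <- osteo_panel()[osteo_panel()$gene == "NF1", ]
  bp <- sim$breakpoints[sim$breakpoints$sample == "S004", ]
  in_fp <- (bp$chrom1 == nf1$chrom & bp$pos1 >= nf1$start &
              bp$pos1 < nf1$end) |
    (bp$chrom2 == nf1$chrom & bp$pos2 >= nf1$start & bp$pos2 < nf1$end)
  expect_true(any(in_fp))
})

test_that("planting a driver on a quiet genome is rejected", {
  cfg <- small_config(
    14L,
    planted_drivers = data.frame(sample = "S001", gene = "MDM2",
                                 mechanism = "amplification",
                                 stringsAsFactors = FALSE))
  expect_error(simulate_cohort(cfg), "contradictory config")
})

test_that("expression follows copy dosage exactly when noiseless", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      start = c(10e6, 30e6), end = c(10.01e6, 30.01e6),
                      stringsAsFactors = FALSE)
  base <- c(G1 = 50, G2 = 8)
  seg <- chromamp:::.splice_segment(seg_df("S1", "chr1", 0, 60e6, 1, 1),
                                    29e6, 31e6, 3L, 1L)
  tpm <- simulate_expression(seg, genes, base, ploidy = 2L, sigma = 0,
                             delta = 0)
  expect_equal(tpm[["G1"]], 50)        # CN = ploidy: baseline exactly
  expect_equal(tpm[["G2"]], 16)        # total CN 4, diploid: 2x baseline
  expect_error(
    simulate_expression(seg_df("S1", "chr2", 0, 1e6, 1, 1), genes, base, 2L),
    "not covered")
})

test_that("extra dispersion raises log-expression variance in CA regions", {
  genes <- data.frame(gene = c("CA_G", "NEU_G"), chrom = "chr1",
                      start = c(10e6, 30e6), end = c(10.01e6, 30.01e6),
                      stringsAsFactors = FALSE)
  base <- c(CA_G = 10, NEU_G = 10)
  seg <- seg_df("S1", "chr1", 0, 60e6, 1, 1)
  ca <- data.frame(chrom = "chr1", start = 9e6, end = 11e6,
                   stringsAsFactors = FALSE)
  set.seed(99)
  draws <- replicate(1000, simulate_expression(seg, genes, base, 2L,
                                               sigma = 0.3, delta = 0.6,
                                               ca_regions = ca))
  expect_gt(var(log(draws["CA_G", ])), var(log(draws["NEU_G", ])))
})
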