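test_that("ploidy class uses the length-weighted mean with a >= 3 cutoff", {
  expect_equal(classify_ploidy(seg_df("S", "chr1", 0, 1e6, 1, 1))$class,
               "diploid")
  expect_equal(classify_ploidy(seg_df("S", "chr1", 0, 1e6, 2, 2))$class,
               "tetraploid")
  half <- rbind(seg_df("S", "chr1", 0, 1e6, 1, 1),
                seg_df("S", "chr1", 1e6, 2e6, 2, 2))
  p <- classify_ploidy(half)
  expect_equal(p$mean_cn, 3)
  expect_equal(p$class, "tetraploid")  # boundary is inclusive
  expect_error(classify_ploidy(seg_df(character(), character(), numeric(),
                                      numeric(), integer(), integer())),
               "no segments")
})

test_that("amplification calls require the threshold and strict focality", {
  panel <- toy_panel()
  onc <- panel[panel$role == "oncogene", ]
  dip <- list(class = "diploid", ploidy = 2L)
  tet <- list(class = "tetraploid", ploidy = 4L)

  base <- toy_background()
  amp04 <- chromamp:::.splice_segment(base, 9.9e6, 10.3e6, 11L, 1L)
  expect_equal(call_amplification(onc, amp04, dip)$mechanism, "amplification")

  # qualifying run spanning exactly 1 Mb: rejected (strict <)
  amp1 <- chromamp:::.splice_segment(base, 9.8e6, 10.8e6, 11L, 1L)
  expect_null(call_amplification(onc, amp1, dip))

  # tetraploid at total CN 8: below the 9-copy threshold
  amp8 <- chromamp:::.splice_segment(seg_df("S1", "chr1", 0, 60e6, 2, 2),
                                     9.9e6, 10.3e6, 7L, 1L)
  expect_null(call_amplification(onc, amp8, tet))
  # ...but 9 copies suffice
  amp9 <- chromamp:::.splice_segment(seg_df("S1", "chr1", 0, 60e6, 2, 2),
                                     9.9e6, 10.3e6, 8L, 1L)
  expect_equal(call_amplification(onc, amp9, tet)$mechanism, "amplification")

  # adjacent qualifying segments extend the run beyond 1 Mb: rejected
  split_amp <- chromamp:::.splice_segment(
    chromamp:::.splice_segment(base, 9.8e6, 10.3e6, 11L, 1L),
    10.3e6, 10.9e6, 7L, 1L)
  expect_null(call_amplification(onc, split_amp, dip))
})

test_that("homozygous deletions must be focal and overlap the footprint", {
  rec <- toy_panel()[2, ]
  base <- toy_background()
  hit <- chromamp:::.splice_segment(base, 30.1e6, 30.3e6, 0L, 0L)
  expect_equal(call_homozygous_deletion(rec, hit)$mechanism,
               "homozygous_deletion")
  broad <- chromamp:::.splice_segment(base, 29.5e6, 31.5e6, 0L, 0L)
  expect_null(call_homozygous_deletion(rec, broad))
  away <- chromamp:::.splice_segment(base, 40e6, 40.2e6, 0L, 0L)
  expect_null(call_homozygous_deletion(rec, away))
})

test_that("disruptive breakpoints use the half-open footprint boundary", {
  rec <- toy_panel()[2, ]  # [30e6, 30.3e6)
  inside <- bp_df("S1", "chr1", 30e6, "+", "chr1", 45e6, "-")
  expect_equal(call_disruptive_breakpoint(rec, inside)$mechanism,
               "disruptive_breakpoint")
  upstream <- bp_df("S1", "chr1", 30e6 - 1, "+", "chr1", 45e6, "-")
  expect_null(call_disruptive_breakpoint(rec, upstream))
  translo <- bp_df("S1", "chr1", 30.1e6, "+", "chr9", 5e6, "+")
  expect_equal(call_disruptive_breakpoint(rec, translo)$mechanism,
               "disruptive_breakpoint")
})

test_that("point-mutation rules split by gene role", {
  panel <- toy_panel()
  rec <- panel[2, ]; onc <- panel[1, ]
  fs <- mut_df("S1", "chr1", 30.1e6, "AT", "A", "out_of_frame_indel", "REC1")
  expect_equal(call_point_driver(rec, fs)$mechanism, "truncating_point")
  ms <- mut_df("S1", "chr1", 30.1e6, "G", "A", "missense", "REC1")
  expect_null(call_point_driver(rec, ms))
  off_hs <- mut_df("S1", "chr1", 10.1e6, "G", "A", "missense", "ONC1")
  expect_null(call_point_driver(onc, off_hs))
  at_hs <- mut_df("S1", "chr1", 10050000, "G", "T", "missense", "ONC1")
  expect_equal(call_point_driver(onc, at_hs)$mechanism, "hotspot_point")
})

test_that("curate_drivers unions mechanisms and deduplicates", {
  panel <- toy_panel()
  seg <- chromamp:::.splice_segment(toy_background(), 30.1e6, 30.2e6, 0L, 0L)
  bp <- bp_df("S1", "chr1", 30.05e6, "+", "chr1", 50e6, "-")
  mut <- rbind(
    mut_df("S1", "chr1", 30.1e6, "AT", "A", "out_of_frame_indel", "REC1"),
    mut_df("S1", "chr1", 30.15e6, "C", "CA", "out_of_frame_indel", "REC1"))
  drv <- curate_drivers(seg, bp, mut, panel)
  expect_equal(drv$mechanism,
               c("disruptive_breakpoint", "homozygous_deletion",
                 "truncating_point"))
  # two truncating mutations collapse into one event with joint evidence
  expect_equal(sum(drv$mechanism == "truncating_point"), 1L)
  expect_match(drv$evidence[drv$mechanism == "truncating_point"], ";")

  expect_equal(nrow(curate_drivers(seg, bp, mut, panel[0, ])), 0L)
})

test_that("raising amplification thresholds never adds events", {
  for (seed in 1:5) {
    rc <- random_cohort(4L, seed)
    lo <- curate_drivers(rc$segments, rc$breakpoints, rc$mutations, rc$panel,
                         driver_rules())
    hi <- curate_drivers(rc$segments, rc$breakpoints, rc$mutations, rc$panel,
                         driver_rules(min_amp_cn_diploid = 7L,
                                      min_amp_cn_tetraploid = 11L))
    amp_lo <- lo[lo$mechanism == "amplification", ]
    amp_hi <- hi[hi$mechanism == "amplification", ]
    expect_true(all(paste(amp_hi$sample, amp_hi$gene) %in%
                      paste(amp_lo$sample, amp_lo$gene)))
  }
})

test_that("allele-specific report encodes gains, LOH and breakpoints", {
  panel <- osteo_panel()
  cops3 <- panel[panel$gene == "COPS3", ]
  tert <- panel[panel$gene == "TERT", ]
  tp53 <- panel[panel$gene == "TP53", ]
  seg <- rbind(
    seg_df("X1", cops3$chrom, cops3$start, cops3$end, 14, 1),
    seg_df("X1", tert$chrom, tert$start, tert$end, 2, 1),
    seg_df("X1", tp53$chrom, tp53$start, tp53$end, 2, 0))
  bp <- bp_df("X1", "chr17", (tp53$start + tp53$end) / 2, "+",
              "chr17", 12e6, "-")
  rep <- allele_specific_report(panel, seg, bp)
  expect_equal(rep$call[rep$gene == "COPS3"], "+13")
  expect_true(rep$significant[rep$gene == "COPS3"])
  expect_equal(rep$call[rep$gene == "TERT"], "+1")
  expect_false(rep$significant[rep$gene == "TERT"])
  expect_equal(rep$call[rep$gene == "TP53"], "LOH+BP")
  # uncovered panel genes yield no call
  expect_equal(sort(rep$gene), c("COPS3", "TERT", "TP53"))
})

test_that("rule engine matches the brute-force oracle on random cohorts", {
  for (seed in 1:6) {
    rc <- random_cohort(5L, seed)
    got <- curate_drivers(rc$segments, rc$breakpoints, rc$mutations, rc$panel)
    want <- oracle_drivers(rc$segments, rc$breakpoints, rc$mutations,
                           rc$panel)
    expect_equal(got[, c("sample", "gene", "mechanism")], want,
                 ignore_attr = TRUE)
  }
})
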