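test_that("quartile variance matches hand computation and scales as c^2", {
  rv <- tpm_quartile_variance(1:5)
  expect_equal(rv$quartiles, c(2, 3, 4))
  expect_equal(rv$variance, 1)

  expect_equal(tpm_quartile_variance(rep(7, 10))$variance, 0)

  set.seed(3)
  x <- rexp(20)
  expect_equal(tpm_quartile_variance(3 * x)$variance,
               9 * tpm_quartile_variance(x)$variance)

  expect_null(tpm_quartile_variance(1:4))       # below min_genes
  expect_error(tpm_quartile_variance(c(-1, 1:9)), "non-negative")
})

test_that("region comparison uses group medians with ties excluded", {
  expect_equal(compare_region(4, 1), 1L)
  expect_equal(compare_region(1, 4), 0L)
  expect_true(is.na(compare_region(c(1, 3), c(2, 2))))
  expect_true(is.na(compare_region(numeric(), 1)))
})

test_that("binomial sign test is exact", {
  expect_equal(binomial_sign_test(0, 10)$p_value, 1)
  expect_equal(binomial_sign_test(8, 10)$p_value, 56 / 1024)
  for (n in c(1, 5, 15)) {
    expect_equal(binomial_sign_test(n, n)$p_value, 0.5^n)
  }
  expect_error(binomial_sign_test(0, 0), "n must be >= 1")
})

test_that("exact p matches brute-force enumeration for all n <= 15", {
  for (n in c(1, 2, 3, 7, 10, 15)) {
    # enumerate all 2^n equally likely sign patterns
    counts <- vapply(0:(2^n - 1), function(b) {
      sum(bitwAnd(b, 2^(0:(n - 1))) > 0)
    }, numeric(1))
    for (k in 0:n) {
      expect_equal(binomial_sign_test(k, n)$p_value, mean(counts >= k))
    }
  }
})

test_that("p is non-increasing in k at fixed n", {
  for (n in c(4, 9, 15)) {
    p <- vapply(0:n, function(k) binomial_sign_test(k, n)$p_value, numeric(1))
    expect_true(all(diff(p) <= 0))
  }
})

test_that("the cohort test pipelines regions and handles degenerate input", {
  prof <- data.frame(sample = c("A", "B"), chrom = "chr1",
                     class = c("chromothripsis_amplification", "none"),
                     n_breakpoints = c(20L, 0L), n_cn_states = c(2L, 1L),
                     amplified_segment_count = c(2L, 0L),
                     region_start = c(10e6, NA), region_end = c(20e6, NA),
                     stringsAsFactors = FALSE)
  reg <- data.frame(chrom = "chr1", start = 10e6, end = 20e6,
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene = paste0("G", 1:6), chrom = "chr1",
                      start = seq(11e6, 16e6, by = 1e6),
                      end = seq(11e6, 16e6, by = 1e6) + 1e4,
                      stringsAsFactors = FALSE)
  set.seed(8)
  tpm <- matrix(rexp(12, 0.1), nrow = 6,
                dimnames = list(genes$gene, c("A", "B")))
  res <- run_expression_test(prof, reg, tpm, genes)
  expect_equal(res$status, "ok")
  expect_equal(res$result$n_regions_tested, 1L)
  expect_true(res$result$p_value %in% c(0.5, 1))

  empty <- run_expression_test(prof, reg[0, ], tpm, genes)
  expect_equal(empty$status, "no test performed")
})

test_that("the test is powered against planted extra dispersion", {
  set.seed(17)
  p <- replicate(100,
                 simulate_expression_sign_test(n_regions = 20L,
                                               delta = 0.6)$p_value)
  expect_gte(mean(p < 0.05), 0.8)
})
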