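# Expression variability in recurrently chromothripsis-amplified regions:
# per sample and region, the variance of the three TPM quartiles over the
# region's genes; per region, a comparison of median variance between
# chromothripsis-amplified and copy-number-neutral samples; cohort-wide, an
# exact one-sided binomial sign test of the 50% null.

#' Variance of the TPM quartiles for one region/sample
#'
#' Computes Q1/Q2/Q3 of the gene TPMs (linear interpolation,
#' `stats::quantile` type 7) and the sample variance (denominator 2) of those
#' three values.
#'
#' @param tpm Non-negative TPM values of the genes in one region for one
#'   sample.
#' @param min_genes Minimum number of genes required. Default 5.
#' @return A list with `quartiles` (length 3) and `variance`, or `NULL` when
#'   fewer than `min_genes` values are supplied (the region is skipped).
#' @export
tpm_quartile_variance <- function(tpm, min_genes = 5L) {
  if (length(tpm) < min_genes) return(NULL)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  q <- stats::quantile(tpm, probs = c(0.25, 0.5, 0.75), names = FALSE)
  list(quartiles = q, variance = stats::var(q))
}

#' Compare quartile-variance between groups for one region
#'
#' Indicator is 1 iff the median variance of the chromothripsis-amplified
#' samples exceeds the median of the copy-number-neutral samples, 0 for the
#' reverse; exact ties or an empty group return `NA` (region excluded from
#' the sign test).
#'
#' @param var_ca Variances of the chromothripsis-amplified samples.
#' @param var_neutral Variances of the copy-number-neutral samples.
#' @return 1, 0 or `NA`.
#' @export
compare_region <- function(var_ca, var_neutral) {
  if (length(var_ca) == 0L || length(var_neutral) == 0L) return(NA)
  m_ca <- stats::median(var_ca)
  m_n <- stats::median(var_neutral)
  if (m_ca == m_n) return(NA)
  as.integer(m_ca > m_n)
}

#' Exact one-sided binomial sign test
#'
#' Tests the null that chromothripsis-amplified samples show the higher
#' median variance in 50% of regions against the one-sided alternative of a
#' higher proportion: `p = P(X >= k)` for `X ~ Binomial(n, 1/2)`.
#'
#' @param k Number of regions where the chromothripsis-amplified group had
#'   the higher median variance.
#' @param n Number of regions tested.
#' @return A list with `n_regions_tested`, `k_ca_higher`, `null_prob` (0.5)
#'   and `p_value`.
#' @export
binomial_sign_test <- function(k, n) {
  if (n < 1L) stop("nothing tested: n must be >= 1")
  if (k < 0L || k > n) stop("k must be between 0 and n")
  p <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  list(n_regions_tested = as.integer(n), k_ca_higher = as.integer(k),
       null_prob = 0.5, p_value = p)
}

#' Cohort expression-variance test over recurrent regions
#'
#' For each recurrent chromothripsis-amplified region: collects the region's
#' genes from the annotation, computes each sample's TPM-quartile variance,
#' splits samples into a chromothripsis-amplified group (chromosome classed
#' `chromothripsis_amplification` with the amplified region overlapping the
#' test region) and a copy-number-neutral group (chromosome classed `none`),
#' compares group medians, and finally runs the binomial sign test over all
#' regions with a defined comparison.
#'
#' @param chrom_profiles Per-chromosome profile table from [profile_cohort()].
#' @param regions Region table from [recurrent_ca_regions()] (columns
#'   `chrom`, `start`, `end`).
#' @param tpm Expression matrix (genes x samples).
#' @param gene_coords Gene annotation `data.frame` with columns `gene`,
#'   `chrom`, `start`, `end` for (at least) the rows of `tpm`.
#' @param min_genes Minimum genes per testable region. Default 5.
#' @return A list with `status` (`"ok"` or `"no test performed"`), `regions`
#'   (per-region table with `k` indicator and group sizes) and `result`
#'   (a [binomial_sign_test()] list, or `NULL`).
#' @export
run_expression_test <- function(chrom_profiles, regions, tpm, gene_coords,
                                min_genes = 5L) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]; r0 <- regions$start[i]; r1 <- regions$end[i]
    genes <- gene_coords$gene[gene_coords$chrom == ch &
                                gene_coords$start < r1 &
                                gene_coords$end > r0]
    genes <- intersect(genes, rownames(tpm))
    prof <- chrom_profiles[chrom_profiles$chrom == ch, , drop = FALSE]
    ca_samples <- prof$sample[prof$class == "chromothripsis_amplification" &
                                !is.na(prof$region_start) &
                                prof$region_start < r1 & prof$region_end > r0]
    neutral_samples <- prof$sample[prof$class == "none"]
    ca_samples <- intersect(ca_samples, colnames(tpm))
    neutral_samples <- intersect(neutral_samples, colnames(tpm))
    region_id <- sprintf("%s:%d-%d", ch, r0, r1)
    if (length(genes) < min_genes) {
      message("region ", region_id, " skipped: fewer than ", min_genes,
              " genes")
      next
    }
    vars <- function(samples) {
      v <- vapply(samples, function(s) {
        tpm_quartile_variance(tpm[genes, s], min_genes)$variance
      }, numeric(1))
      v
    }
    if (length(ca_samples) == 0L || length(neutral_samples) == 0L) {
      message("region ", region_id, " excluded: empty comparison group")
      next
    }
    ind <- compare_region(vars(ca_samples), vars(neutral_samples))
    rows[[length(rows) + 1L]] <- data.frame(
      region = region_id, chrom = ch, start = r0, end = r1,
      n_genes = length(genes), n_ca = length(ca_samples),
      n_neutral = length(neutral_samples), ca_higher = ind,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(status = "no test performed", regions = NULL, result = NULL))
  }
  tab <- do.call(rbind, rows)
  tested <- !is.na(tab$ca_higher)
  if (!any(tested)) {
    return(list(status = "no test performed", regions = tab, result = NULL))
  }
  res <- binomial_sign_test(sum(tab$ca_higher[tested]), sum(tested))
  list(status = "ok", regions = tab, result = res)
}
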