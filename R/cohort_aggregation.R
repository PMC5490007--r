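# Cohort-aggregate copy-number profiling: per-sample binned log2 copy-number
# ratios, the cross-sample mean / first quartile / third quartile profile,
# and recurrently chromothripsis-amplified regions with their target genes.

#' Binned log2 copy-number ratio for one sample/chromosome
#'
#' Tiles the chromosome with `bin_size` bins and computes, per bin,
#' `log2(length-weighted mean total CN / ploidy)`. Gaps between segments are
#' imputed at ploidy. Bins whose weighted mean CN is 0 are clamped at a
#' configurable floor.
#'
#' @param segments Segments of one sample/chromosome.
#' @param ploidy Sample ploidy (2 or 4); the normalisation denominator.
#' @param chrom_length Chromosome length in bases.
#' @param bin_size Bin width in bases. Default 1e6.
#' @param floor_cn Copy number substituted for 0 before taking logs.
#'   Default 0.5.
#' @return A `data.frame` with columns `bin_start`, `bin_end`, `log2_ratio`.
#' @export
bin_log_ratio <- function(segments, ploidy, chrom_length, bin_size = 1e6,
                          floor_cn = 0.5) {
  starts <- seq(0, chrom_length - 1, by = bin_size)
  ends <- pmin(starts + bin_size, chrom_length)
  seg <- segments[order(segments$start), , drop = FALSE]
  ratio <- vapply(seq_along(starts), function(i) {
    b0 <- starts[i]; b1 <- ends[i]
    ovl <- seg[seg$start < b1 & seg$end > b0, , drop = FALSE]
    w <- pmin(ovl$end, b1) - pmax(ovl$start, b0)
    covered <- sum(w)
    total <- sum(w * ovl$total_cn) + (b1 - b0 - covered) * ploidy
    mean_cn <- total / (b1 - b0)
    log2(max(mean_cn, floor_cn) / ploidy)
  }, numeric(1))
  data.frame(bin_start = starts, bin_end = ends, log2_ratio = ratio)
}

#' Aggregate binned profiles across a cohort
#'
#' Given a bins x samples matrix of log2 ratios, returns the per-bin mean and
#' first/third quartiles across samples (quantiles by linear interpolation
#' between order statistics, `stats::quantile` type 7).
#'
#' @param bin_matrix Numeric matrix, one row per bin, one column per sample.
#' @return A `data.frame` with columns `mean`, `q1`, `q3` (one row per bin).
#' @export
aggregate_profile <- function(bin_matrix) {
  stopifnot(is.matrix(bin_matrix), ncol(bin_matrix) >= 1L)
  data.frame(
    mean = rowMeans(bin_matrix),
    q1 = apply(bin_matrix, 1, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(bin_matrix, 1, stats::quantile, probs = 0.75, names = FALSE)
  )
}

#' Aggregate copy-number profile of a cohort for one chromosome
#'
#' Convenience wrapper: bins every sample with [bin_log_ratio()] (using each
#' sample's own ploidy) and aggregates with [aggregate_profile()].
#'
#' @param segments Cohort segment table.
#' @param ploidies Named vector of sample ploidies (2/4).
#' @param chrom Chromosome to profile.
#' @param chrom_length Its length in bases.
#' @param bin_size Bin width. Default 1e6.
#' @return A `data.frame` with `chrom`, `bin_start`, `bin_end`, `mean`, `q1`,
#'   `q3`.
#' @export
chromosome_aggregate <- function(segments, ploidies, chrom, chrom_length,
                                 bin_size = 1e6) {
  samples <- sort(unique(segments$sample))
  cols <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s & segments$chrom == chrom, ,
                    drop = FALSE]
    bin_log_ratio(seg, ploidies[[s]], chrom_length, bin_size)$log2_ratio
  })
  m <- do.call(cbind, cols)
  colnames(m) <- samples
  bins <- bin_log_ratio(.empty_segments(), 2, chrom_length, bin_size)
  cbind(data.frame(chrom = chrom, bin_start = bins$bin_start,
                   bin_end = bins$bin_end, stringsAsFactors = FALSE),
        aggregate_profile(m))
}

#' Recurrently chromothripsis-amplified regions
#'
#' Bins each chromosome and counts, per bin, the samples whose
#' chromothripsis-amplified region (breakpoint-cluster span of a chromosome
#' classed `chromothripsis_amplification`) overlaps the bin. Adjacent
#' qualifying bins (count >= `min_samples`) are merged into maximal half-open
#' intervals and annotated with overlapping panel genes.
#'
#' @param chrom_profiles Per-chromosome profile table from [profile_cohort()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param min_samples Recurrence threshold. Default 3.
#' @param bin_size Bin width. Default 1e6.
#' @param panel Optional gene panel for target-gene annotation.
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `n_samples_ca`, `target_genes` (comma-separated, may be empty).
#' @export
recurrent_ca_regions <- function(chrom_profiles, chrom_lengths,
                                 min_samples = 3L, bin_size = 1e6,
                                 panel = NULL) {
  ca <- chrom_profiles[chrom_profiles$class == "chromothripsis_amplification" &
                         !is.na(chrom_profiles$region_start), , drop = FALSE]
  out <- list()
  for (ch in sort(unique(ca$chrom))) {
    cc <- ca[ca$chrom == ch, , drop = FALSE]
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    counts <- vapply(seq_along(starts), function(i) {
      sum(cc$region_start < ends[i] & cc$region_end > starts[i])
    }, numeric(1))
    qual <- counts >= min_samples
    if (!any(qual)) next
    r <- rle(qual)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- idx_start[j]; i1 <- idx_end[j]
      genes <- ""
      if (!is.null(panel)) {
        hit <- panel$chrom == ch & panel$start < ends[i1] &
          panel$end > starts[i0]
        genes <- paste(panel$gene[hit], collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[i0], end = ends[i1],
        n_samples_ca = max(counts[i0:i1]), target_genes = genes,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_samples_ca = numeric(), target_genes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Plot an aggregate copy-number profile
#'
#' Mean line with a Q1-Q3 band, in the style of cohort copy-number landscape
#' figures. Requires ggplot2.
#'
#' @param agg Output of [chromosome_aggregate()].
#' @return A ggplot object.
#' @export
plot_aggregate_profile <- function(agg) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  mb <- (agg$bin_start + agg$bin_end) / 2 / 1e6
  df <- data.frame(mb = mb, mean = agg$mean, q1 = agg$q1, q3 = agg$q3)
  ggplot2::ggplot(df, ggplot2::aes(x = mb)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q1, ymax = q3),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = mean), colour = "black") +
    ggplot2::labs(x = "Genomic position (Mb)",
                  y = "Copy number change (log2)") +
    ggplot2::theme_classic()
}
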