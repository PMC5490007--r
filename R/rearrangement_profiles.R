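# Classification of chromosomes and genomes into three cytogenetic
# configurations: quiet, chromothripsis (many clustered breakpoints with
# copy number oscillating among few states), and chromothripsis
# amplification (the same oscillation interleaved with high-level focal
# amplicons reaching the ploidy-specific amplification threshold).

#' Chromothripsis-detection parameters
#'
#' The published descriptions of chromothripsis are qualitative; these
#' operational criteria quantify them and are fully configurable.
#'
#' @param min_breakpoints Minimum rearrangement ends on a chromosome.
#'   Default 10.
#' @param max_cn_states Maximum distinct total-CN states among oscillating
#'   (non-amplified) segments. Default 3.
#' @param min_oscillating_segments Minimum length of the longest run of
#'   consecutive segments whose total CN changes at every step. Default 10.
#' @param quiet_genome_max_breakpoints Genome-wide breakpoint-end budget for
#'   the quiet class. Default 5.
#' @param amp_interleave_min Minimum number of amplified segments inside the
#'   chromothriptic region for the amplification upgrade. Default 1.
#' @param min_segment_length Segments shorter than this (bases) are ignored
#'   when counting CN states and oscillation, to avoid noise-driven state
#'   inflation. Default 1e4.
#' @param cluster_gap Maximum gap (bases) between consecutive breakpoint ends
#'   within one cluster; the chromothriptic region is the span of the largest
#'   cluster. Default 1e7.
#' @return A list of class `ct_params`.
#' @export
chromothripsis_params <- function(min_breakpoints = 10L,
                                  max_cn_states = 3L,
                                  min_oscillating_segments = 10L,
                                  quiet_genome_max_breakpoints = 5L,
                                  amp_interleave_min = 1L,
                                  min_segment_length = 1e4,
                                  cluster_gap = 1e7) {
  stopifnot(min_breakpoints > 0, max_cn_states > 0,
            min_oscillating_segments > 0, quiet_genome_max_breakpoints >= 0,
            amp_interleave_min > 0, min_segment_length >= 0, cluster_gap > 0)
  structure(as.list(environment()), class = "ct_params")
}

# all rearrangement end positions falling on `chrom`
.breakpoint_ends <- function(breakpoints, chrom) {
  pos <- c(breakpoints$pos1[breakpoints$chrom1 == chrom],
           breakpoints$pos2[breakpoints$chrom2 == chrom])
  sort(pos)
}

# span (start, end) of the largest cluster of positions with gaps <= gap
.largest_cluster <- function(pos, gap) {
  if (length(pos) == 0L) return(NULL)
  brk <- which(diff(pos) > gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(pos))
  k <- which.max(ends - starts)
  c(start = pos[starts[k]], end = pos[ends[k]], n = ends[k] - starts[k] + 1L)
}

#' Count distinct total-copy-number states on a chromosome
#'
#' @param segments Sorted, non-overlapping segments of one chromosome.
#' @param min_segment_length Segments shorter than this are ignored.
#' @return Number of distinct total-CN values (0 for no segments).
#' @export
count_cn_states <- function(segments, min_segment_length = 1e4) {
  keep <- (segments$end - segments$start) >= min_segment_length
  length(unique(segments$total_cn[keep]))
}

# longest run of consecutive (length-filtered) segments in which total CN
# changes at every adjacent step
.oscillation_run <- function(total_cn) {
  n <- length(total_cn)
  if (n == 0L) return(0L)
  best <- run <- 1L
  for (i in seq_len(n - 1L)[n > 1L]) {
    run <- if (total_cn[i + 1L] != total_cn[i]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

.profile_row <- function(sample, chrom, class, n_bkpt, n_states, n_amp,
                         region_start, region_end) {
  data.frame(sample = sample, chrom = chrom, class = class,
             n_breakpoints = n_bkpt, n_cn_states = n_states,
             amplified_segment_count = n_amp,
             region_start = region_start, region_end = region_end,
             stringsAsFactors = FALSE)
}

# core single-chromosome profiler; amp_threshold = NULL disables the
# amplification upgrade (and the exclusion of amplified segments from the
# oscillation criteria)
.profile_chromosome <- function(segments, breakpoints, params,
                                amp_threshold = NULL) {
  chrom <- if (nrow(segments)) segments$chrom[1] else
    if (nrow(breakpoints)) breakpoints$chrom1[1] else NA_character_
  sample <- if (nrow(segments)) segments$sample[1] else
    if (nrow(breakpoints)) breakpoints$sample[1] else NA_character_
  ends <- .breakpoint_ends(breakpoints, chrom)
  n_bkpt <- length(ends)
  cluster <- .largest_cluster(ends, params$cluster_gap)
  seg <- segments[order(segments$start), , drop = FALSE]
  keep <- (seg$end - seg$start) >= params$min_segment_length
  seg <- seg[keep, , drop = FALSE]
  amp <- if (is.null(amp_threshold)) rep(FALSE, nrow(seg))
         else seg$total_cn >= amp_threshold
  base <- seg[!amp, , drop = FALSE]
  n_states <- length(unique(base$total_cn))
  run <- .oscillation_run(base$total_cn)
  is_ct <- n_bkpt >= params$min_breakpoints &&
    n_states <= params$max_cn_states && n_states > 0L &&
    run >= params$min_oscillating_segments
  n_amp_in_region <- 0L
  region_start <- region_end <- NA_real_
  if (!is.null(cluster)) {
    region_start <- cluster[["start"]]
    region_end <- cluster[["end"]]
    if (any(amp)) {
      a <- seg[amp, , drop = FALSE]
      n_amp_in_region <- sum(a$start < region_end & a$end > region_start)
    }
  }
  class <- if (is_ct && n_amp_in_region >= params$amp_interleave_min)
    "chromothripsis_amplification" else if (is_ct) "chromothripsis" else "none"
  .profile_row(sample, chrom, class, n_bkpt, n_states,
               n_amp_in_region, region_start, region_end)
}

#' Detect chromothripsis on one chromosome
#'
#' A chromosome is chromothriptic iff it carries at least
#' `min_breakpoints` rearrangement ends, its (length-filtered) segments show
#' at most `max_cn_states` distinct total-CN values, and at least
#' `min_oscillating_segments` consecutive segments alternate in total CN.
#' Counts are reported regardless of class.
#'
#' @param segments Segments of a single sample/chromosome.
#' @param breakpoints Breakpoints of the same sample (any chromosome; ends on
#'   this chromosome are counted).
#' @param params A [chromothripsis_params()] object.
#' @return One-row profile `data.frame` with columns `sample`, `chrom`,
#'   `class`, `n_breakpoints`, `n_cn_states`, `amplified_segment_count`,
#'   `region_start`, `region_end`.
#' @export
detect_chromothripsis <- function(segments, breakpoints,
                                  params = chromothripsis_params()) {
  .profile_chromosome(segments, breakpoints, params, amp_threshold = NULL)
}

#' Detect chromothripsis amplification on one chromosome
#'
#' Evaluates the chromothripsis criteria with segments at or above the
#' ploidy-specific amplification threshold set aside, then upgrades the class
#' to `chromothripsis_amplification` iff at least `amp_interleave_min` such
#' amplified segments lie inside the chromothriptic region (the span of the
#' largest breakpoint cluster).
#'
#' @inheritParams detect_chromothripsis
#' @param ploidy Result of [classify_ploidy()] for the sample.
#' @param rules A [driver_rules()] object (supplies the 5/9-copy thresholds).
#' @return One-row profile `data.frame` (see [detect_chromothripsis()]).
#' @export
detect_chromothripsis_amplification <- function(segments, breakpoints, ploidy,
                                                rules = driver_rules(),
                                                params = chromothripsis_params()) {
  thr <- amplification_threshold(ploidy$class, rules)
  .profile_chromosome(segments, breakpoints, params, amp_threshold = thr)
}

#' Classify a genome from its per-chromosome profiles
#'
#' Precedence: `chromothripsis_amplification` if any chromosome carries it,
#' else `chromothripsis` if any chromosome does, else `quiet` when the
#' genome-wide breakpoint-end count is within the quiet budget; genomes that
#' are rearranged beyond the budget but non-chromothriptic are classed `quiet`
#' = FALSE with the explicit flag `rearranged_non_chromothriptic`.
#'
#' @param profiles Per-chromosome profile `data.frame` for one sample.
#' @param params A [chromothripsis_params()] object.
#' @return A list with `sample`, `class` (`quiet` / `chromothripsis` /
#'   `chromothripsis_amplification` / `rearranged_non_chromothriptic`) and
#'   `chromosomes` (the input profiles).
#' @export
classify_genome <- function(profiles, params = chromothripsis_params()) {
  total_bkpt <- sum(profiles$n_breakpoints)
  class <- if (any(profiles$class == "chromothripsis_amplification")) {
    "chromothripsis_amplification"
  } else if (any(profiles$class == "chromothripsis")) {
    "chromothripsis"
  } else if (total_bkpt <= params$quiet_genome_max_breakpoints) {
    "quiet"
  } else {
    "rearranged_non_chromothriptic"
  }
  list(sample = profiles$sample[1], class = class,
       n_breakpoints = total_bkpt, chromosomes = profiles)
}

#' Profile every chromosome and genome of a cohort
#'
#' Runs ploidy classification, per-chromosome chromothripsis(-amplification)
#' detection and genome classification over all samples.
#'
#' @param segments Cohort segment table.
#' @param breakpoints Cohort breakpoint table.
#' @param rules A [driver_rules()] object.
#' @param params A [chromothripsis_params()] object.
#' @return A list with `chromosomes` (per-sample/chromosome profile table)
#'   and `genomes` (per-sample table with columns `sample`, `class`,
#'   `n_breakpoints`, `ploidy_class`, `mean_cn`).
#' @export
profile_cohort <- function(segments, breakpoints, rules = driver_rules(),
                           params = chromothripsis_params()) {
  chrom_rows <- list()
  genome_rows <- list()
  for (s in sort(unique(segments$sample))) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    bp <- breakpoints[breakpoints$sample == s, , drop = FALSE]
    ploidy <- classify_ploidy(seg, rules)
    chroms <- sort(unique(c(seg$chrom, bp$chrom1, bp$chrom2)))
    profs <- do.call(rbind, lapply(chroms, function(ch) {
      p <- detect_chromothripsis_amplification(
        seg[seg$chrom == ch, , drop = FALSE], bp, ploidy, rules, params)
      p$sample <- s
      p$chrom <- ch
      p
    }))
    g <- classify_genome(profs, params)
    chrom_rows[[s]] <- profs
    genome_rows[[s]] <- data.frame(sample = s, class = g$class,
                                   n_breakpoints = g$n_breakpoints,
                                   ploidy_class = ploidy$class,
                                   mean_cn = ploidy$mean_cn,
                                   stringsAsFactors = FALSE)
  }
  chromosomes <- do.call(rbind, chrom_rows)
  genomes <- do.call(rbind, genome_rows)
  rownames(chromosomes) <- rownames(genomes) <- NULL
  list(chromosomes = chromosomes, genomes = genomes)
}
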