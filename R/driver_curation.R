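# Rule-based curation of somatic driver events in established cancer genes.
#
# Recessive genes are hit by truncating point mutations (truncating
# substitutions, out-of-frame indels, splice-disrupting variants), focal
# (<1 Mb) homozygous deletions, or rearrangement breakpoints falling inside
# the gene footprint. Oncogenes are hit by point mutations at canonical
# hotspots or by focal (<1 Mb) amplifications raising the whole gene to at
# least 5 copies (diploid genomes) or 9 copies (tetraploid genomes).

#' Driver-curation rule thresholds
#'
#' @param focality_threshold Maximum span (bases) of a focal event; strict
#'   `<`. Default 1e6.
#' @param min_amp_cn_diploid Minimum total copy number an amplification must
#'   reach in a diploid genome. Default 5.
#' @param min_amp_cn_tetraploid Minimum total copy number in a tetraploid
#'   genome. Default 9.
#' @param truncating_consequences Consequence terms counted as truncating a
#'   recessive gene.
#' @param significant_gain_extra_copies Minimum extra major-allele copies for
#'   a gain to be flagged significant in allele-specific target-gene reports.
#'   Default 2.
#' @param tetraploid_cutoff Length-weighted mean total copy number at or above
#'   which a genome is classed tetraploid. Default 3.
#' @return A list of class `driver_rules`.
#' @export
driver_rules <- function(focality_threshold = 1e6,
                         min_amp_cn_diploid = 5L,
                         min_amp_cn_tetraploid = 9L,
                         truncating_consequences = c("truncating_substitution",
                                                     "out_of_frame_indel",
                                                     "splice_disrupting"),
                         significant_gain_extra_copies = 2L,
                         tetraploid_cutoff = 3) {
  stopifnot(focality_threshold > 0, min_amp_cn_diploid > 0,
            min_amp_cn_tetraploid > min_amp_cn_diploid,
            significant_gain_extra_copies >= 0, tetraploid_cutoff > 0)
  structure(list(focality_threshold = focality_threshold,
                 min_amp_cn_diploid = as.integer(min_amp_cn_diploid),
                 min_amp_cn_tetraploid = as.integer(min_amp_cn_tetraploid),
                 truncating_consequences = truncating_consequences,
                 significant_gain_extra_copies =
                   as.integer(significant_gain_extra_copies),
                 tetraploid_cutoff = tetraploid_cutoff),
            class = "driver_rules")
}

#' Read driver rules from a YAML file
#' @param path YAML file whose keys match the arguments of [driver_rules()].
#' @return A `driver_rules` object.
#' @export
read_driver_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(driver_rules, cfg)
}

#' Classify a sample as diploid or tetraploid
#'
#' Computes the length-weighted mean total copy number over all segments of
#' one sample; class is `tetraploid` iff the mean is at or above
#' `rules$tetraploid_cutoff` (default 3), else `diploid`.
#'
#' @param segments Segment table for a single sample.
#' @param rules A [driver_rules()] object.
#' @return A list with `class` ("diploid"/"tetraploid"), `mean_cn`, `ploidy`
#'   (2 or 4).
#' @export
classify_ploidy <- function(segments, rules = driver_rules()) {
  if (nrow(segments) == 0L) stop("cannot classify ploidy: no segments")
  w <- segments$end - segments$start
  mean_cn <- sum(w * segments$total_cn) / sum(w)
  cls <- if (mean_cn >= rules$tetraploid_cutoff) "tetraploid" else "diploid"
  list(class = cls, mean_cn = mean_cn,
       ploidy = if (cls == "tetraploid") 4L else 2L)
}

#' Ploidy-specific amplification copy-number threshold
#' @param ploidy_class `"diploid"` or `"tetraploid"`.
#' @param rules A [driver_rules()] object.
#' @return Integer minimum total copy number.
#' @export
amplification_threshold <- function(ploidy_class, rules = driver_rules()) {
  if (ploidy_class == "tetraploid") rules$min_amp_cn_tetraploid
  else rules$min_amp_cn_diploid
}

# segments of one sample overlapping [start, end) on chrom
.overlapping_segments <- function(segments, chrom, start, end) {
  sel <- segments$chrom == chrom & segments$start < end & segments$end > start
  segments[sel, , drop = FALSE]
}

# TRUE iff the overlapping segments jointly cover every base of [start, end)
.footprint_covered <- function(ovl, start, end) {
  if (nrow(ovl) == 0L) return(FALSE)
  ovl <- ovl[order(ovl$start), , drop = FALSE]
  if (ovl$start[1] > start) return(FALSE)
  if (nrow(ovl) > 1L && any(ovl$start[-1] > ovl$end[-nrow(ovl)])) return(FALSE)
  max(ovl$end) >= end
}

#' Call a focal oncogene amplification
#'
#' An event is called iff the entire gene footprint lies within segments whose
#' total copy number reaches the ploidy-specific threshold (5 diploid / 9
#' tetraploid) and the maximal run of contiguous qualifying segments
#' containing the gene spans strictly less than the focality threshold (1 Mb):
#' the amplification must be focal and amplify the intact gene.
#'
#' @param gene One row of a gene panel (role `oncogene`).
#' @param segments Segment table for the sample.
#' @param ploidy Result of [classify_ploidy()].
#' @param rules A [driver_rules()] object.
#' @return A one-row driver-event `data.frame`, or `NULL`.
#' @export
call_amplification <- function(gene, segments, ploidy, rules = driver_rules()) {
  stopifnot(gene$role == "oncogene")
  thr <- amplification_threshold(ploidy$class, rules)
  ovl <- .overlapping_segments(segments, gene$chrom, gene$start, gene$end)
  if (nrow(ovl) == 0L) {
    warning("gene ", gene$gene, " not covered by any segment")
    return(NULL)
  }
  if (!.footprint_covered(ovl, gene$start, gene$end)) return(NULL)
  if (any(ovl$total_cn < thr)) return(NULL)
  # maximal contiguous run of qualifying segments containing the gene
  chr <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  chr <- chr[order(chr$start), , drop = FALSE]
  q <- chr$total_cn >= thr
  idx <- which(chr$start < gene$end & chr$end > gene$start)
  lo <- min(idx); hi <- max(idx)
  while (lo > 1L && q[lo - 1L] && chr$end[lo - 1L] == chr$start[lo]) lo <- lo - 1L
  while (hi < nrow(chr) && q[hi + 1L] && chr$start[hi + 1L] == chr$end[hi]) hi <- hi + 1L
  span <- chr$end[hi] - chr$start[lo]
  if (span >= rules$focality_threshold) return(NULL)
  .driver_event(segments$sample[1], gene$gene, "amplification",
                sprintf("%s:%.0f-%.0f CN>=%d span %.0f bp", gene$chrom,
                        chr$start[lo], chr$end[hi], thr, span))
}

#' Call a focal homozygous deletion of a recessive gene
#'
#' An event is called iff a segment with total copy number 0 and span strictly
#' below the focality threshold overlaps the gene footprint.
#'
#' @inheritParams call_amplification
#' @return A one-row driver-event `data.frame`, or `NULL`.
#' @export
call_homozygous_deletion <- function(gene, segments, rules = driver_rules()) {
  stopifnot(gene$role == "recessive")
  ovl <- .overlapping_segments(segments, gene$chrom, gene$start, gene$end)
  if (nrow(ovl) == 0L) {
    warning("gene ", gene$gene, " not covered by any segment")
    return(NULL)
  }
  hit <- ovl[ovl$total_cn == 0 &
               (ovl$end - ovl$start) < rules$focality_threshold, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  .driver_event(segments$sample[1], gene$gene, "homozygous_deletion",
                paste(sprintf("%s:%.0f-%.0f CN0", hit$chrom, hit$start, hit$end),
                      collapse = ";"))
}

#' Call a disruptive rearrangement breakpoint in a recessive gene
#'
#' An event is called iff any rearrangement end falls inside the half-open
#' gene footprint `[start, end)`; for translocations one end inside the
#' footprint suffices.
#'
#' @param gene One row of a gene panel (role `recessive`).
#' @param breakpoints Breakpoint table for the sample.
#' @return A one-row driver-event `data.frame`, or `NULL`.
#' @export
call_disruptive_breakpoint <- function(gene, breakpoints) {
  stopifnot(gene$role == "recessive")
  if (nrow(breakpoints) == 0L) return(NULL)
  in1 <- breakpoints$chrom1 == gene$chrom &
    breakpoints$pos1 >= gene$start & breakpoints$pos1 < gene$end
  in2 <- breakpoints$chrom2 == gene$chrom &
    breakpoints$pos2 >= gene$start & breakpoints$pos2 < gene$end
  hit <- breakpoints[in1 | in2, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  .driver_event(hit$sample[1], gene$gene, "disruptive_breakpoint",
                paste(sprintf("%s:%.0f|%s:%.0f %s", hit$chrom1, hit$pos1,
                              hit$chrom2, hit$pos2, hit$sv_class),
                      collapse = ";"))
}

#' Call a driver point mutation
#'
#' For recessive genes, any annotated mutation of the gene whose consequence
#' is in the truncating set qualifies. For oncogenes, a mutation qualifies iff
#' its (position, alt) pair matches a configured canonical hotspot.
#'
#' @param gene One row of a gene panel.
#' @param mutations Mutation table for the sample.
#' @param rules A [driver_rules()] object.
#' @return A one-row driver-event `data.frame`, or `NULL`.
#' @export
call_point_driver <- function(gene, mutations, rules = driver_rules()) {
  if (nrow(mutations) == 0L) return(NULL)
  mg <- mutations[mutations$gene == gene$gene, , drop = FALSE]
  if (nrow(mg) == 0L) return(NULL)
  if (gene$role == "recessive") {
    hit <- mg[mg$consequence %in% rules$truncating_consequences, , drop = FALSE]
    mech <- "truncating_point"
  } else {
    hs <- gene$hotspots[[1]]
    key <- paste(mg$pos, mg$alt)
    hit <- mg[key %in% paste(hs$pos, hs$alt), , drop = FALSE]
    mech <- "hotspot_point"
  }
  if (nrow(hit) == 0L) return(NULL)
  .driver_event(hit$sample[1], gene$gene, mech,
                paste(sprintf("%s:%.0f %s>%s %s", hit$chrom, hit$pos,
                              hit$ref, hit$alt, hit$consequence),
                      collapse = ";"))
}

.driver_event <- function(sample, gene, mechanism, evidence) {
  data.frame(sample = sample, gene = gene, mechanism = mechanism,
             evidence = evidence, stringsAsFactors = FALSE)
}

.empty_drivers <- function() {
  data.frame(sample = character(), gene = character(), mechanism = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' Curate driver events for a cohort
#'
#' Applies the four call types (hotspot/truncating point mutations, focal
#' amplification, focal homozygous deletion, disruptive breakpoint) over every
#' panel gene and sample, deduplicates per (sample, gene, mechanism) with
#' evidence concatenated, and returns events in deterministic order. Each
#' mechanism is only permitted for the matching gene role.
#'
#' @param segments Cohort segment table.
#' @param breakpoints Cohort breakpoint table.
#' @param mutations Cohort mutation table.
#' @param panel Gene panel from [read_gene_panel()].
#' @param rules A [driver_rules()] object.
#' @return A driver-event `data.frame` with columns `sample`, `gene`,
#'   `mechanism`, `evidence`.
#' @export
curate_drivers <- function(segments, breakpoints, mutations, panel,
                           rules = driver_rules()) {
  samples <- sort(unique(c(segments$sample, breakpoints$sample,
                           mutations$sample)))
  out <- list()
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    bp <- breakpoints[breakpoints$sample == s, , drop = FALSE]
    mut <- mutations[mutations$sample == s, , drop = FALSE]
    ploidy <- if (nrow(seg)) classify_ploidy(seg, rules) else NULL
    for (i in seq_len(nrow(panel))) {
      gene <- panel[i, , drop = FALSE]
      ev <- list(call_point_driver(gene, mut, rules))
      if (gene$role == "oncogene") {
        if (!is.null(ploidy)) {
          ev <- c(ev, list(suppressWarnings(
            call_amplification(gene, seg, ploidy, rules))))
        }
      } else {
        if (nrow(seg)) {
          ev <- c(ev, list(suppressWarnings(
            call_homozygous_deletion(gene, seg, rules))))
        }
        ev <- c(ev, list(call_disruptive_breakpoint(gene, bp)))
      }
      out <- c(out, ev)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_drivers())
  ev <- do.call(rbind, out)
  # dedupe per (sample, gene, mechanism), concatenating evidence
  key <- paste(ev$sample, ev$gene, ev$mechanism, sep = "\r")
  agg <- tapply(ev$evidence, key, paste, collapse = ";")
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  ev <- data.frame(sample = parts[, 1], gene = parts[, 2],
                   mechanism = parts[, 3], evidence = unname(agg),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$sample, ev$gene, ev$mechanism), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Allele-specific target-gene report
#'
#' For each sample and reported gene: oncogenes are reported as the number of
#' extra major-allele copies over the footprint (`+N`, minimum across
#' overlapping segments; `-` when zero), flagged significant when the gain
#' reaches `rules$significant_gain_extra_copies`. Recessive (tumour
#' suppressor) genes are reported on the minor allele: `LOH` when the minor
#' allele is 0 over the full footprint, `BP` when a rearrangement end falls in
#' the footprint, `LOH+BP` for both, `-` for neither. Genes whose footprint is
#' not fully covered by a sample's segments yield no call for that sample.
#'
#' @param panel Gene panel (the genes to report).
#' @param segments Cohort segment table.
#' @param breakpoints Cohort breakpoint table.
#' @param rules A [driver_rules()] object.
#' @return A `data.frame` with columns `sample`, `gene`, `role`,
#'   `extra_major`, `loh`, `bp`, `call`, `significant`.
#' @export
allele_specific_report <- function(panel, segments, breakpoints,
                                   rules = driver_rules()) {
  out <- list()
  for (s in sort(unique(segments$sample))) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    bps <- breakpoints[breakpoints$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(panel))) {
      gene <- panel[i, , drop = FALSE]
      ovl <- .overlapping_segments(seg, gene$chrom, gene$start, gene$end)
      if (!.footprint_covered(ovl, gene$start, gene$end)) next
      if (gene$role == "oncogene") {
        extra <- min(ovl$major_cn) - 1L
        out[[length(out) + 1L]] <- data.frame(
          sample = s, gene = gene$gene, role = gene$role,
          extra_major = extra, loh = NA, bp = NA,
          call = if (extra > 0L) paste0("+", extra) else "-",
          significant = extra >= rules$significant_gain_extra_copies,
          stringsAsFactors = FALSE)
      } else {
        loh <- all(ovl$minor_cn == 0L)
        has_bp <- !is.null(call_disruptive_breakpoint(gene, bps))
        call <- if (loh && has_bp) "LOH+BP" else if (loh) "LOH"
                else if (has_bp) "BP" else "-"
        out[[length(out) + 1L]] <- data.frame(
          sample = s, gene = gene$gene, role = gene$role,
          extra_major = NA_integer_, loh = loh, bp = has_bp,
          call = call, significant = NA, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(), gene = character(),
                      role = character(), extra_major = integer(),
                      loh = logical(), bp = logical(), call = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$sample, res$gene), , drop = FALSE]
}
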