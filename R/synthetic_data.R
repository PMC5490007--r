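# Synthetic-cohort generator with planted truth.
#
# Emulates the three cytogenetic configurations of the osteosarcoma genome:
# quiet chromosomes (a single segment at ploidy), chromothriptic chromosomes
# (clustered breakpoints with total copy number oscillating between a
# retained and a lost state), and chromothripsis-amplified chromosomes (the
# same oscillation with interleaved focal amplicons at or above the
# ploidy-specific amplification threshold). Driver events of every curation
# rule class are planted on rearranged genomes, and gene expression is
# coupled to copy dosage with multiplicative log-normal noise plus extra
# dispersion in chromothripsis-amplified regions. All random positions avoid
# panel-gene footprints so that planted truth is recoverable exactly.

#' Simulation configuration
#'
#' @param n_samples Cohort size. Default 40.
#' @param class_counts Named counts of planted genome classes
#'   (`quiet`, `chromothripsis`, `chromothripsis_amplification`); must sum to
#'   `n_samples`. Default `c(4, 11, 25)`.
#' @param ploidy_mix Fraction of tetraploid genomes. Default 0.3.
#' @param chrom_lengths Named chromosome lengths. Default: the GRCh37
#'   chromosomes carrying the bundled panel.
#' @param ca_windows Named list of recurrent chromothripsis-amplification
#'   windows (start, end) per chromosome.
#' @param ct_windows Named list of chromothripsis windows per chromosome.
#' @param n_ct_segments Oscillating segments per chromothriptic region.
#'   Default 20.
#' @param seg_len_range Log-uniform segment-length range (bases).
#'   Default c(8e4, 8e5).
#' @param n_amplicons Amplicons per chromothripsis-amplified region.
#'   Default 3.
#' @param amp_extra_cn_range Amplicon total CN is the ploidy-specific
#'   threshold plus a uniform draw from this range. Default c(0, 15).
#' @param window_jitter Uniform jitter (bases) applied to window edges per
#'   sample. Default 2e6.
#' @param n_passenger_mutations Passenger point mutations per sample.
#'   Default 20.
#' @param expr_baseline_meanlog,expr_baseline_sdlog Log-normal parameters of
#'   per-gene baseline TPM.
#' @param expr_sigma Multiplicative log-normal noise sd. Default 0.3.
#' @param expr_delta Extra dispersion added to `expr_sigma` for genes in
#'   chromothripsis-amplified regions. Default 0.6.
#' @param gene_spacing,gene_width Spacing and width of the synthetic
#'   expression gene catalog. Defaults 1e6 / 1e4.
#' @param planted_drivers Optional `data.frame` with columns `sample`
#'   (identifiers `S001`...), `gene`, `mechanism` overriding the automatic
#'   one-driver-per-rearranged-genome assignment. Planting a driver on a
#'   genome whose planted class is `quiet` is a contradictory configuration
#'   and raises an error.
#' @param panel Gene panel. Default [osteo_panel()].
#' @param rules Driver rules (supply the amplification thresholds).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 40L,
                              class_counts = c(quiet = 4L,
                                               chromothripsis = 11L,
                                               chromothripsis_amplification = 25L),
                              ploidy_mix = 0.3,
                              chrom_lengths = grch37_chrom_lengths()[
                                c("chr2", "chr3", "chr5", "chr6", "chr12",
                                  "chr15", "chr17")],
                              ca_windows = list(chr5 = c(100e6, 120e6),
                                                chr12 = c(85e6, 100e6),
                                                chr17 = c(40e6, 60e6)),
                              ct_windows = list(chr2 = c(30e6, 50e6),
                                                chr3 = c(60e6, 80e6),
                                                chr6 = c(40e6, 60e6),
                                                chr15 = c(30e6, 50e6)),
                              n_ct_segments = 20L,
                              seg_len_range = c(8e4, 8e5),
                              n_amplicons = 3L,
                              amp_extra_cn_range = c(0, 15),
                              window_jitter = 2e6,
                              n_passenger_mutations = 20L,
                              expr_baseline_meanlog = log(10),
                              expr_baseline_sdlog = 1,
                              expr_sigma = 0.3,
                              expr_delta = 0.6,
                              gene_spacing = 1e6,
                              gene_width = 1e4,
                              planted_drivers = NULL,
                              panel = osteo_panel(),
                              rules = driver_rules(),
                              seed = 1L) {
  stopifnot(n_samples >= 0, sum(class_counts) == n_samples,
            ploidy_mix >= 0, ploidy_mix <= 1,
            n_ct_segments > 0, n_amplicons > 0,
            seg_len_range[1] > 0, seg_len_range[2] >= seg_len_range[1])
  structure(as.list(environment()), class = "sim_config")
}

# log-uniform draw
.rlogunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# splice a new segment [start, end) into a sorted single-chromosome segment
# table, truncating/splitting/dropping whatever it overlaps
.splice_segment <- function(seg, start, end, major, minor) {
  keep <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, , drop = FALSE]
    if (s$end <= start || s$start >= end) {         # untouched
      keep[[length(keep) + 1L]] <- s
    } else {
      if (s$start < start) {
        left <- s; left$end <- start
        keep[[length(keep) + 1L]] <- left
      }
      if (s$end > end) {
        right <- s; right$start <- end
        keep[[length(keep) + 1L]] <- right
      }
    }
  }
  new <- seg[1, , drop = FALSE]
  new$start <- start; new$end <- end
  new$major_cn <- as.integer(major); new$minor_cn <- as.integer(minor)
  new$total_cn <- as.integer(major + minor)
  out <- do.call(rbind, c(keep, list(new)))
  out[order(out$start), , drop = FALSE]
}

.seg_row <- function(sample, chrom, start, end, major, minor) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             major_cn = as.integer(major), minor_cn = as.integer(minor),
             total_cn = as.integer(major + minor), stringsAsFactors = FALSE)
}

.bp_row <- function(sample, chrom1, pos1, strand1, chrom2, pos2, strand2) {
  data.frame(sample = sample, chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             stringsAsFactors = FALSE)
}

#' Simulate one chromosome of a planted class
#'
#' Quiet: a single segment at ploidy and no breakpoints. Chromothripsis:
#' `n_ct_segments` segments inside the window alternating between the
#' retained state (ploidy) and a lost state (ploidy - 1), with one
#' rearrangement end per segment boundary. Chromothripsis amplification: the
#' same plus `n_amplicons` interleaved focal amplicons (width < 1 Mb) at or
#' above `amp_threshold`, each anchored at a segment boundary and backed by a
#' tandem-duplication-type rearrangement.
#'
#' @param class `"quiet"`, `"chromothripsis"` or
#'   `"chromothripsis_amplification"`.
#' @param sample_id Sample identifier.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length (bases).
#' @param ploidy 2 or 4.
#' @param window `c(start, end)` region for the rearrangement cluster
#'   (ignored for quiet).
#' @param config A [simulation_config()] object.
#' @param amp_threshold Minimum amplicon total CN (ploidy-specific).
#' @return A list with `segments`, `breakpoints` and `region`
#'   (`c(start, end)` of the rearranged window, or `NULL` for quiet).
#' @export
simulate_chromosome <- function(class, sample_id, chrom, chrom_length, ploidy,
                                window = NULL,
                                config = simulation_config(),
                                amp_threshold = 5L) {
  half <- ploidy %/% 2L
  if (class == "quiet") {
    return(list(segments = .seg_row(sample_id, chrom, 0, chrom_length, half, half),
                breakpoints = NULL, region = NULL))
  }
  if (!class %in% c("chromothripsis", "chromothripsis_amplification")) {
    stop("unknown chromosome class: ", class)
  }
  w0 <- round(window[1]); w1 <- round(window[2])
  n_seg <- config$n_ct_segments
  len_hi <- min(config$seg_len_range[2], (w1 - w0) / n_seg)
  lens <- .rlogunif(n_seg, config$seg_len_range[1], len_hi)
  bounds <- round(w0 + cumsum(c(0, lens)))
  r1 <- bounds[n_seg + 1L]
  # alternating lost/retained states, lost first (flanks are at ploidy)
  lost_major <- half - ifelse(ploidy == 2L, 0L, 1L)
  lost_minor <- ifelse(ploidy == 2L, half - 1L, half)
  seg <- list()
  if (w0 > 0) seg[[1L]] <- .seg_row(sample_id, chrom, 0, w0, half, half)
  for (i in seq_len(n_seg)) {
    if (i %% 2L == 1L) {
      seg[[length(seg) + 1L]] <- .seg_row(sample_id, chrom, bounds[i],
                                          bounds[i + 1L],
                                          max(lost_major, lost_minor),
                                          min(lost_major, lost_minor))
    } else {
      seg[[length(seg) + 1L]] <- .seg_row(sample_id, chrom, bounds[i],
                                          bounds[i + 1L], half, half)
    }
  }
  if (r1 < chrom_length) {
    seg[[length(seg) + 1L]] <- .seg_row(sample_id, chrom, r1, chrom_length,
                                        half, half)
  }
  segments <- do.call(rbind, seg)
  # one rearrangement end per boundary, paired sequentially; odd boundary
  # paired with a random partner inside the region
  pos <- bounds
  if (length(pos) %% 2L == 1L) {
    pos <- c(pos, round(stats::runif(1, w0, r1)))
  }
  pos <- sample(pos)
  bp <- list()
  for (i in seq(1L, length(pos), by = 2L)) {
    bp[[length(bp) + 1L]] <- .bp_row(
      sample_id, chrom, pos[i], sample(c("+", "-"), 1L),
      chrom, pos[i + 1L], sample(c("+", "-"), 1L))
  }
  if (class == "chromothripsis_amplification") {
    # anchor each amplicon at the left edge of a distinct interior segment,
    # leaving >= 20 kb of the host so the oscillation run survives
    host_ok <- which(lens >= 1.5 * config$seg_len_range[1])
    hosts <- host_ok[sample.int(length(host_ok),
                                min(config$n_amplicons, length(host_ok)))]
    for (h in hosts) {
      host_len <- bounds[h + 1L] - bounds[h]
      width <- round(stats::runif(1, 0.4, 0.7) * host_len)
      width <- min(width, 9e5)
      a0 <- bounds[h]; a1 <- a0 + width
      cn <- amp_threshold +
        round(stats::runif(1, config$amp_extra_cn_range[1],
                           config$amp_extra_cn_range[2]))
      segments <- .splice_segment(segments, a0, a1, cn - 1L, 1L)
      bp[[length(bp) + 1L]] <- .bp_row(sample_id, chrom, a0, "-",
                                       chrom, a1, "+")
    }
  }
  list(segments = segments, breakpoints = do.call(rbind, bp),
       region = c(w0, r1))
}

# synthetic expression gene catalog: genes at regular spacing, skipping
# panel footprints
.gene_catalog <- function(chrom_lengths, spacing, width, panel) {
  rows <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(spacing, chrom_lengths[[ch]] - spacing, by = spacing)
    for (k in seq_along(starts)) {
      g0 <- starts[k]; g1 <- g0 + width
      if (any(panel$chrom == ch & panel$start < g1 & panel$end > g0)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sprintf("G_%s_%03d", sub("^chr", "", ch), k),
        chrom = ch, start = g0, end = g1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate dosage-coupled expression for one sample
#'
#' `tpm(g) = baseline(g) * (total_cn(g) / ploidy) * exp(N(0, sigma^2))`, with
#' `sigma` replaced by `sigma + delta` for genes inside chromothripsis-
#' amplified regions. The copy number of a gene is that of the segment
#' containing its midpoint; an uncovered midpoint is an error.
#'
#' @param segments Segment table for the sample.
#' @param genes Gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param baselines Named baseline TPM vector (one entry per gene).
#' @param ploidy 2 or 4.
#' @param sigma Log-normal noise sd.
#' @param delta Extra dispersion in chromothripsis-amplified regions.
#' @param ca_regions Optional `data.frame` (`chrom`, `start`, `end`) of the
#'   sample's chromothripsis-amplified regions.
#' @return Named numeric vector of TPMs.
#' @export
simulate_expression <- function(segments, genes, baselines, ploidy,
                                sigma = 0.3, delta = 0,
                                ca_regions = NULL) {
  mid <- (genes$start + genes$end) / 2
  tpm <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    sel <- segments$chrom == genes$chrom[i] & segments$start <= mid[i] &
      segments$end > mid[i]
    if (!any(sel)) stop("gene ", genes$gene[i], " not covered by any segment")
    cn <- segments$total_cn[which(sel)[1]]
    in_ca <- !is.null(ca_regions) && nrow(ca_regions) > 0 &&
      any(ca_regions$chrom == genes$chrom[i] & ca_regions$start <= mid[i] &
            ca_regions$end > mid[i])
    sd_i <- if (in_ca) sigma + delta else sigma
    noise <- if (sd_i > 0) exp(stats::rnorm(1, 0, sd_i)) else 1
    tpm[i] <- baselines[[genes$gene[i]]] * (cn / ploidy) * noise
  }
  names(tpm) <- genes$gene
  tpm
}

# driver templates cycled over rearranged samples
.driver_templates <- function() {
  data.frame(
    gene = c("IGF1R", "MDM2", "TP53", "IGF2R", "NF1", "PIK3CA", "RICTOR",
             "IGFBP5", "CDK4", "TP53", "IGF2R"),
    mechanism = c("amplification", "amplification", "homozygous_deletion",
                  "truncating_point", "disruptive_breakpoint", "hotspot_point",
                  "amplification", "homozygous_deletion", "amplification",
                  "disruptive_breakpoint", "truncating_point"),
    stringsAsFactors = FALSE)
}

# realise one planted driver on a sample, mutating segments/breakpoints/
# mutations in place (returned as a list)
.plant_driver <- function(state, sample_id, gene_row, mechanism, ploidy, rules) {
  g <- gene_row
  half <- ploidy %/% 2L
  if (mechanism == "amplification") {
    thr <- amplification_threshold(
      if (ploidy == 4L) "tetraploid" else "diploid", rules)
    cn <- thr + 3L
    a0 <- g$start - 2e4; a1 <- g$end + 2e4
    stopifnot(a1 - a0 < rules$focality_threshold)
    chr <- state$segments[[g$chrom]]
    state$segments[[g$chrom]] <- .splice_segment(chr, a0, a1, cn - half, half)
  } else if (mechanism == "homozygous_deletion") {
    d0 <- g$start - 1e4
    d1 <- min(g$start + 1.5e5, g$end + 1e4)
    chr <- state$segments[[g$chrom]]
    state$segments[[g$chrom]] <- .splice_segment(chr, d0, d1, 0L, 0L)
  } else if (mechanism == "disruptive_breakpoint") {
    mid <- round((g$start + g$end) / 2)
    state$breakpoints[[length(state$breakpoints) + 1L]] <-
      .bp_row(sample_id, g$chrom, mid, "+", g$chrom, mid + 3e6, "-")
  } else if (mechanism == "truncating_point") {
    state$mutations[[length(state$mutations) + 1L]] <- data.frame(
      sample = sample_id, chrom = g$chrom, pos = round((g$start + g$end) / 2),
      ref = "AT", alt = "A", variant_type = "indel",
      consequence = "out_of_frame_indel", gene = g$gene,
      stringsAsFactors = FALSE)
  } else if (mechanism == "hotspot_point") {
    hs <- g$hotspots[[1]]
    if (nrow(hs) == 0L) stop("no hotspot configured for oncogene ", g$gene)
    state$mutations[[length(state$mutations) + 1L]] <- data.frame(
      sample = sample_id, chrom = g$chrom, pos = hs$pos[1],
      ref = "G", alt = hs$alt[1], variant_type = "substitution",
      consequence = "missense", gene = g$gene, stringsAsFactors = FALSE)
  } else {
    stop("unknown planted mechanism: ", mechanism)
  }
  state
}

# passenger mutations, rejection-sampled outside panel footprints
.passenger_mutations <- function(sample_id, n, chrom_lengths, panel) {
  if (n == 0L) return(NULL)
  chroms <- sample(names(chrom_lengths), n, replace = TRUE)
  pos <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p <- round(stats::runif(1, 1, chrom_lengths[[chroms[i]]] - 1))
      hit <- panel$chrom == chroms[i] & panel$start <= p & panel$end > p
      if (!any(hit)) break
    }
    pos[i] <- p
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(sample = sample_id, chrom = chroms, pos = pos, ref = ref, alt = alt,
             variant_type = "substitution",
             consequence = sample(c("missense", "synonymous", "other"), n,
                                  replace = TRUE),
             gene = "", stringsAsFactors = FALSE)
}

#' Simulate a cohort with planted truth
#'
#' Generates per-sample copy-number segments, rearrangement breakpoints,
#' point mutations and a dosage-coupled TPM expression matrix under the
#' planted genome classes of `config`, plants one driver event (cycling
#' through every rule class) on each rearranged genome, and returns the truth
#' set. With `out_dir` set, all tables are also written in the package's file
#' schemas plus a `truth.json`.
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Optional output directory.
#' @return A list with `segments`, `breakpoints`, `mutations`, `tpm`,
#'   `gene_catalog`, `truth` (list with `genomes`, `chromosomes`, `drivers`,
#'   `ca_regions`) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  panel <- config$panel
  rules <- config$rules
  classes <- rep(names(config$class_counts), config$class_counts)
  n <- config$n_samples
  samples <- if (n > 0) sprintf("S%03d", seq_len(n)) else character()
  catalog <- .gene_catalog(config$chrom_lengths, config$gene_spacing,
                           config$gene_width, panel)
  baselines <- stats::setNames(
    exp(stats::rnorm(nrow(catalog), config$expr_baseline_meanlog,
                     config$expr_baseline_sdlog)),
    catalog$gene)
  templates <- .driver_templates()
  tmpl_i <- 0L
  planted <- config$planted_drivers
  if (!is.null(planted)) {
    cls_of <- stats::setNames(classes, samples)
    bad <- planted$sample[cls_of[planted$sample] == "quiet" |
                            is.na(cls_of[planted$sample])]
    if (length(bad)) {
      stop("contradictory config: driver planted on quiet or unknown ",
           "genome(s): ", paste(unique(bad), collapse = ", "))
    }
  }

  seg_all <- list(); bp_all <- list(); mut_all <- list()
  tpm_cols <- list()
  truth_g <- list(); truth_c <- list(); truth_d <- list(); truth_r <- list()

  for (si in seq_len(n)) {
    s <- samples[si]
    cls <- classes[si]
    ploidy <- if (stats::runif(1) < config$ploidy_mix) 4L else 2L
    thr <- amplification_threshold(
      if (ploidy == 4L) "tetraploid" else "diploid", rules)
    # chromosome assignment
    chrom_class <- stats::setNames(rep("quiet", length(config$chrom_lengths)),
                                   names(config$chrom_lengths))
    if (cls == "chromothripsis") {
      picks <- sample(names(config$ct_windows), sample(1:2, 1L))
      chrom_class[picks] <- "chromothripsis"
    } else if (cls == "chromothripsis_amplification") {
      picks <- sample(names(config$ca_windows), sample(1:2, 1L))
      chrom_class[picks] <- "chromothripsis_amplification"
      if (stats::runif(1) < 0.4) {
        extra <- sample(names(config$ct_windows), 1L)
        chrom_class[extra] <- "chromothripsis"
      }
    }
    state <- list(segments = list(), breakpoints = list(), mutations = list())
    ca_regions <- list()
    for (ch in names(config$chrom_lengths)) {
      ch_cls <- chrom_class[[ch]]
      win <- NULL
      if (ch_cls != "quiet") {
        base_win <- if (ch_cls == "chromothripsis") config$ct_windows[[ch]]
                    else config$ca_windows[[ch]]
        jit <- stats::runif(1, -config$window_jitter, config$window_jitter)
        win <- base_win + jit
      }
      sim <- simulate_chromosome(ch_cls, s, ch, config$chrom_lengths[[ch]],
                                 ploidy, win, config, thr)
      state$segments[[ch]] <- sim$segments
      if (!is.null(sim$breakpoints)) {
        state$breakpoints[[length(state$breakpoints) + 1L]] <- sim$breakpoints
      }
      truth_c[[length(truth_c) + 1L]] <- data.frame(
        sample = s, chrom = ch, class = ch_cls, stringsAsFactors = FALSE)
      if (ch_cls == "chromothripsis_amplification") {
        ca_regions[[length(ca_regions) + 1L]] <- data.frame(
          sample = s, chrom = ch, start = sim$region[1], end = sim$region[2],
          stringsAsFactors = FALSE)
      }
    }
    # planted drivers: explicit list, or one per rearranged genome cycling
    # through the rule classes
    plant_here <- if (!is.null(planted)) {
      planted[planted$sample == s, c("gene", "mechanism"), drop = FALSE]
    } else if (cls != "quiet") {
      tmpl_i <- tmpl_i %% nrow(templates) + 1L
      templates[tmpl_i, , drop = FALSE]
    } else {
      templates[0, , drop = FALSE]
    }
    for (di in seq_len(nrow(plant_here))) {
      tm <- plant_here[di, ]
      g <- panel[panel$gene == tm$gene, , drop = FALSE]
      if (nrow(g) != 1L) stop("planted driver gene not in panel: ", tm$gene)
      state <- .plant_driver(state, s, g, tm$mechanism, ploidy, rules)
      truth_d[[length(truth_d) + 1L]] <- data.frame(
        sample = s, gene = tm$gene, mechanism = tm$mechanism,
        stringsAsFactors = FALSE)
    }
    state$mutations[[length(state$mutations) + 1L]] <-
      .passenger_mutations(s, config$n_passenger_mutations,
                           config$chrom_lengths, panel)
    seg_s <- do.call(rbind, state$segments)
    seg_all[[s]] <- seg_s
    if (length(state$breakpoints)) {
      bp_all[[s]] <- do.call(rbind, state$breakpoints)
    }
    mut_s <- do.call(rbind, state$mutations)
    if (!is.null(mut_s)) mut_all[[s]] <- mut_s
    car <- if (length(ca_regions)) do.call(rbind, ca_regions) else NULL
    if (!is.null(car)) truth_r[[length(truth_r) + 1L]] <- car
    tpm_cols[[s]] <- simulate_expression(seg_s, catalog, baselines, ploidy,
                                         config$expr_sigma, config$expr_delta,
                                         car)
    truth_g[[length(truth_g) + 1L]] <- data.frame(
      sample = s, class = cls, ploidy = ploidy, stringsAsFactors = FALSE)
  }

  segments <- if (length(seg_all)) sort_segments(do.call(rbind, seg_all))
              else .empty_segments()
  rownames(segments) <- NULL
  breakpoints <- if (length(bp_all))
    canonicalize_breakpoints(do.call(rbind, bp_all)) else .empty_breakpoints()
  mutations <- if (length(mut_all)) {
    m <- do.call(rbind, mut_all)
    m <- m[order(m$sample, m$chrom, m$pos), , drop = FALSE]
    rownames(m) <- NULL
    m
  } else {
    data.frame(sample = character(), chrom = character(), pos = numeric(),
               ref = character(), alt = character(), variant_type = character(),
               consequence = character(), gene = character(),
               stringsAsFactors = FALSE)
  }
  validate_segments(segments, "simulated cohort")
  tpm <- if (length(tpm_cols)) do.call(cbind, tpm_cols)
         else matrix(numeric(), nrow = nrow(catalog), ncol = 0,
                     dimnames = list(catalog$gene, NULL))
  truth <- list(
    genomes = if (length(truth_g)) do.call(rbind, truth_g) else NULL,
    chromosomes = if (length(truth_c)) do.call(rbind, truth_c) else NULL,
    drivers = if (length(truth_d)) do.call(rbind, truth_d) else NULL,
    ca_regions = if (length(truth_r)) do.call(rbind, truth_r) else NULL)

  result <- list(segments = segments, breakpoints = breakpoints,
                 mutations = mutations, tpm = tpm, gene_catalog = catalog,
                 truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segments(segments, file.path(out_dir, "segments.tsv"))
    write_breakpoints(breakpoints, file.path(out_dir, "breakpoints.bedpe"))
    write_mutations(mutations, file.path(out_dir, "mutations.tsv"))
    write_expression(tpm, file.path(out_dir, "expression.tsv"))
    utils::write.table(catalog, file.path(out_dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

#' Sign test on a simulated expression cohort
#'
#' Generates `n_regions` independent regions of `genes_per_region` genes,
#' draws log-normal TPMs for two groups of samples (a "chromothripsis-
#' amplified" group with noise sd `sigma + delta` and a copy-number-neutral
#' control group with sd `sigma`; both groups are copy-number neutral so that
#' with `delta = 0` the groups are exchangeable and the null of the sign test
#' holds exactly), then runs the full quartile-variance comparison and
#' binomial sign test.
#'
#' @param n_regions Number of regions. Default 20.
#' @param n_ca,n_neutral Group sizes. Defaults 4.
#' @param genes_per_region Genes per region. Default 20.
#' @param sigma Baseline noise sd. Default 0.3.
#' @param delta Extra dispersion of the first group. Default 0 (the null).
#' @param baseline_meanlog,baseline_sdlog Per-gene baseline TPM parameters.
#' @return A [binomial_sign_test()] result list.
#' @export
simulate_expression_sign_test <- function(n_regions = 20L, n_ca = 4L,
                                          n_neutral = 4L,
                                          genes_per_region = 20L,
                                          sigma = 0.3, delta = 0,
                                          baseline_meanlog = log(10),
                                          baseline_sdlog = 1) {
  k <- 0L; n <- 0L
  for (r in seq_len(n_regions)) {
    base <- exp(stats::rnorm(genes_per_region, baseline_meanlog,
                             baseline_sdlog))
    draw <- function(sd) {
      base * exp(stats::rnorm(genes_per_region, 0, sd))
    }
    v_ca <- vapply(seq_len(n_ca), function(i) {
      tpm_quartile_variance(draw(sigma + delta))$variance
    }, numeric(1))
    v_n <- vapply(seq_len(n_neutral), function(i) {
      tpm_quartile_variance(draw(sigma))$variance
    }, numeric(1))
    ind <- compare_region(v_ca, v_n)
    if (!is.na(ind)) {
      n <- n + 1L
      k <- k + ind
    }
  }
  binomial_sign_test(k, n)
}
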