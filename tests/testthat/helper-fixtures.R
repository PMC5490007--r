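# Small in-code fixture builders shared across the suite.

seg_df <- function(sample, chrom, start, end, major, minor) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             major_cn = as.integer(major), minor_cn = as.integer(minor),
             total_cn = as.integer(major + minor), stringsAsFactors = FALSE)
}

bp_df <- function(sample, chrom1, pos1, strand1, chrom2, pos2, strand2) {
  canonicalize_breakpoints(data.frame(
    sample = sample, chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
    chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
    stringsAsFactors = FALSE))
}

mut_df <- function(sample, chrom, pos, ref, alt, consequence, gene) {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_type = ifelse(nchar(ref) != nchar(alt),
                                   "indel", "substitution"),
             consequence = consequence, gene = gene, stringsAsFactors = FALSE)
}

# minimal one-oncogene / one-recessive panel on a toy chromosome
toy_panel <- function() {
  data.frame(gene = c("ONC1", "REC1"),
             chrom = "chr1",
             start = c(10e6, 30e6), end = c(10.2e6, 30.3e6),
             role = c("oncogene", "recessive"),
             hotspots = I(list(
               data.frame(pos = 10050000, alt = "T",
                          stringsAsFactors = FALSE),
               data.frame(pos = numeric(), alt = character(),
                          stringsAsFactors = FALSE))),
             stringsAsFactors = FALSE)
}

# a diploid background covering chr1 with a spliced-in focal event
toy_background <- function(sample = "S1", len = 60e6) {
  seg_df(sample, "chr1", 0, len, 1, 1)
}

write_lines_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small random cohort for property tests (independent of the simulator)
random_cohort <- function(n_samples = 3L, seed = 1L) {
  set.seed(seed)
  panel <- toy_panel()
  segs <- list(); bps <- list(); muts <- list()
  for (i in seq_len(n_samples)) {
    s <- sprintf("P%02d", i)
    base_cn <- sample(c(1L, 2L), 1)  # diploid or tetraploid background
    seg <- seg_df(s, "chr1", 0, 60e6, base_cn, base_cn)
    # random focal events
    for (k in seq_len(sample(0:3, 1))) {
      w <- sample(c(2e5, 5e5, 2e6), 1)
      a0 <- round(runif(1, 0, 60e6 - w))
      cn <- sample(c(0L, 6L, 12L), 1)
      seg <- chromamp:::.splice_segment(seg, a0, a0 + w,
                                        max(cn - 1L, 0L), min(cn, 1L))
    }
    segs[[i]] <- seg
    if (runif(1) < 0.7) {
      p1 <- round(runif(1, 0, 60e6))
      bps[[length(bps) + 1L]] <- bp_df(s, "chr1", p1, "+", "chr1",
                                       p1 + 1e6, "-")
    }
    if (runif(1) < 0.7) {
      muts[[length(muts) + 1L]] <- mut_df(
        s, "chr1", round(runif(1, 30e6, 30.3e6)), "AT", "A",
        sample(c("out_of_frame_indel", "missense"), 1), "REC1")
    }
  }
  list(segments = do.call(rbind, segs),
       breakpoints = if (length(bps)) do.call(rbind, bps)
                     else chromamp:::.empty_breakpoints(),
       mutations = if (length(muts)) do.call(rbind, muts)
                   else mut_df(character(), character(), numeric(),
                               character(), character(), character(),
                               character()),
       panel = panel)
}
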