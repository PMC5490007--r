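# Brute-force oracle: a literal, independent restatement of the curation
# rules, enumerating every (gene, record) pair without any of the package's
# interval machinery. Used to check curate_drivers() on small cohorts.

oracle_ploidy <- function(seg) {
  m <- sum((seg$end - seg$start) * seg$total_cn) / sum(seg$end - seg$start)
  if (m >= 3) "tetraploid" else "diploid"
}

oracle_drivers <- function(segments, breakpoints, mutations, panel,
                           rules = driver_rules()) {
  out <- data.frame(sample = character(), gene = character(),
                    mechanism = character(), stringsAsFactors = FALSE)
  add <- function(s, g, mech) {
    if (!any(out$sample == s & out$gene == g & out$mechanism == mech)) {
      out[nrow(out) + 1L, ] <<- list(s, g, mech)
    }
  }
  samples <- sort(unique(c(segments$sample, breakpoints$sample,
                           mutations$sample)))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    bp <- breakpoints[breakpoints$sample == s, , drop = FALSE]
    mut <- mutations[mutations$sample == s, , drop = FALSE]
    thr <- if (nrow(seg) == 0L) NA
           else if (oracle_ploidy(seg) == "tetraploid")
             rules$min_amp_cn_tetraploid else rules$min_amp_cn_diploid
    for (gi in seq_len(nrow(panel))) {
      g <- panel[gi, ]
      # point mutations, record by record
      for (mi in seq_len(nrow(mut))) {
        m <- mut[mi, ]
        if (m$gene != g$gene) next
        if (g$role == "recessive" &&
            m$consequence %in% rules$truncating_consequences) {
          add(s, g$gene, "truncating_point")
        }
        if (g$role == "oncogene") {
          hs <- g$hotspots[[1]]
          for (hi in seq_len(nrow(hs))) {
            if (m$pos == hs$pos[hi] && m$alt == hs$alt[hi]) {
              add(s, g$gene, "hotspot_point")
            }
          }
        }
      }
      if (g$role == "recessive") {
        for (ki in seq_len(nrow(seg))) {
          k <- seg[ki, ]
          if (k$chrom == g$chrom && k$total_cn == 0 &&
              (k$end - k$start) < rules$focality_threshold &&
              k$start < g$end && k$end > g$start) {
            add(s, g$gene, "homozygous_deletion")
          }
        }
        for (bi in seq_len(nrow(bp))) {
          b <- bp[bi, ]
          hit1 <- b$chrom1 == g$chrom && b$pos1 >= g$start && b$pos1 < g$end
          hit2 <- b$chrom2 == g$chrom && b$pos2 >= g$start && b$pos2 < g$end
          if (hit1 || hit2) add(s, g$gene, "disruptive_breakpoint")
        }
      }
      if (g$role == "oncogene" && nrow(seg) > 0L) {
        # every base of the footprint at CN >= thr, and the containing
        # maximal contiguous qualifying run spans < 1 Mb
        chr <- seg[seg$chrom == g$chrom, , drop = FALSE]
        chr <- chr[order(chr$start), , drop = FALSE]
        cover <- chr[chr$start < g$end & chr$end > g$start, , drop = FALSE]
        covered <- nrow(cover) > 0 && all(cover$total_cn >= thr) &&
          cover$start[1] <= g$start && max(cover$end) >= g$end &&
          (nrow(cover) < 2 ||
             all(cover$start[-1] <= cover$end[-nrow(cover)]))
        if (covered) {
          # grow the run over touching qualifying neighbours
          run_lo <- min(cover$start); run_hi <- max(cover$end)
          repeat {
            grew <- FALSE
            for (ki in seq_len(nrow(chr))) {
              k <- chr[ki, ]
              if (k$total_cn >= thr && k$end == run_lo) {
                run_lo <- k$start; grew <- TRUE
              }
              if (k$total_cn >= thr && k$start == run_hi) {
                run_hi <- k$end; grew <- TRUE
              }
            }
            if (!grew) break
          }
          if (run_hi - run_lo < rules$focality_threshold) {
            add(s, g$gene, "amplification")
          }
        }
      }
    }
  }
  out[order(out$sample, out$gene, out$mechanism), , drop = FALSE]
}
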