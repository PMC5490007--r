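# Bundled reference data: the osteosarcoma cancer-gene panel (GRCh37
# footprints, roles, hotspots) and the published allele-specific copy-number
# calls of putative target genes in regions of chromothripsis amplification,
# together with a constructor that realises those calls as concrete
# segment/breakpoint inputs for validation of the reporting code.

#' GRCh37 autosome lengths
#' @return Named numeric vector of chromosome lengths (bases), chr1..chr22.
#' @export
grch37_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' Bundled osteosarcoma cancer-gene panel
#'
#' Loads the packaged panel (BED footprints + YAML roles/hotspots) of
#' osteosarcoma driver genes: oncogenes TERT, RICTOR, CCND2, CDK4, MDM2,
#' COPS3, IGF1, IGF1R, PIK3CA (with canonical hotspots) and recessive genes
#' TP53, NF1, IGF2R, IGFBP5.
#'
#' @return Panel `data.frame` as returned by [read_gene_panel()].
#' @export
osteo_panel <- function() {
  read_gene_panel(
    system.file("extdata", "osteo_panel.bed", package = "chromamp",
                mustWork = TRUE),
    system.file("extdata", "osteo_panel.yaml", package = "chromamp",
                mustWork = TRUE))
}

#' Published target-gene calls in chromothripsis-amplified regions
#'
#' The allele-specific copy-number calls of putative target genes (TERT,
#' RICTOR on chr5; CCND2, MDM2, CDK4 on chr12; TP53, COPS3, NF1 on chr17)
#' reported for the 12 chromothripsis-amplified osteosarcomas: `+N` = N extra
#' major-allele copies for oncogenes, `LOH`/`BP`/`LOH+BP` for tumour
#' suppressors, `-` = no change. `significant` marks calls with a significant
#' major-allele gain (oncogenes only; `NA` for tumour suppressors).
#'
#' @return A `data.frame` with columns `sample`, `gene`, `call`, `significant`.
#' @export
osteo_target_calls <- function() {
  path <- system.file("extdata", "osteo_target_calls.tsv",
                      package = "chromamp", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}

#' Realise published target-gene calls as segment/breakpoint inputs
#'
#' Constructs, for each sample of the reference call set, allele-specific
#' copy-number segments over the involved gene footprints (one segment per
#' reported gene) and BEDPE-style breakpoints for the `BP` calls, such that
#' running [allele_specific_report()] on the result reproduces every call.
#' Oncogene `+N` becomes major CN `N + 1` (minor 1); `LOH` becomes minor CN 0
#' with major CN 2; `BP` places one rearrangement end at the gene midpoint.
#'
#' @param calls Call table from [osteo_target_calls()].
#' @param panel Gene panel from [osteo_panel()].
#' @return A list with elements `segments` and `breakpoints`.
#' @export
reference_cohort_inputs <- function(calls = osteo_target_calls(),
                                    panel = osteo_panel()) {
  seg <- list()
  bp <- list()
  for (i in seq_len(nrow(calls))) {
    g <- panel[panel$gene == calls$gene[i], ]
    if (nrow(g) != 1L) stop("call for gene absent from panel: ", calls$gene[i])
    call <- calls$call[i]
    has_bp <- FALSE
    if (g$role == "oncogene") {
      extra <- if (call == "-") 0L else as.integer(sub("^\\+", "", call))
      major <- 1L + extra
      minor <- 1L
    } else {
      loh <- grepl("LOH", call)
      has_bp <- grepl("BP", call)
      minor <- if (loh) 0L else 1L
      major <- if (call == "-") 1L else 2L
    }
    seg[[i]] <- data.frame(sample = calls$sample[i], chrom = g$chrom,
                           start = g$start, end = g$end,
                           major_cn = major, minor_cn = minor,
                           total_cn = major + minor,
                           stringsAsFactors = FALSE)
    if (has_bp) {
      mid <- floor((g$start + g$end) / 2)
      bp[[length(bp) + 1L]] <- data.frame(
        sample = calls$sample[i], chrom1 = g$chrom, pos1 = mid,
        strand1 = "+", chrom2 = g$chrom, pos2 = mid + 3e6, strand2 = "-",
        stringsAsFactors = FALSE)
    }
  }
  segments <- sort_segments(do.call(rbind, seg))
  breakpoints <- if (length(bp)) canonicalize_breakpoints(do.call(rbind, bp))
                 else .empty_breakpoints()
  validate_segments(segments, "reference cohort")
  list(segments = segments, breakpoints = breakpoints)
}
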