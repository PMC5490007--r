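# Readers/writers for the tab-separated formats the pipeline consumes:
# allele-specific copy-number segments, BEDPE rearrangement breakpoints,
# consequence-annotated point mutations, gene panels (BED + YAML) and
# gene-level TPM expression matrices.
#
# Coordinate conventions (fixed):
#   * internal representation: 0-based half-open [start, end)
#   * segments / mutations TSV on disk: 1-based inclusive
#   * BEDPE and BED on disk: 0-based half-open (the formats' own convention)

#' Closed vocabulary of mutation consequences
#'
#' @return Character vector of the consequence terms accepted internally.
#' @export
consequence_vocabulary <- function() {
  c("truncating_substitution", "out_of_frame_indel", "in_frame_indel",
    "missense", "synonymous", "splice_disrupting", "other")
}

# VEP/CGP-style synonyms normalised on ingest.
.consequence_synonyms <- c(
  frameshift                = "out_of_frame_indel",
  frameshift_variant        = "out_of_frame_indel",
  stop_gained               = "truncating_substitution",
  nonsense                  = "truncating_substitution",
  stop_lost                 = "truncating_substitution",
  start_lost                = "truncating_substitution",
  ess_splice                = "splice_disrupting",
  splice_site               = "splice_disrupting",
  splice_acceptor_variant   = "splice_disrupting",
  splice_donor_variant      = "splice_disrupting",
  missense_variant          = "missense",
  synonymous_variant        = "synonymous",
  silent                    = "synonymous",
  inframe_insertion         = "in_frame_indel",
  inframe_deletion          = "in_frame_indel"
)

#' Normalise a chromosome name to "chr"-prefixed form
#'
#' Names are accepted with or without the "chr" prefix.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with the "chr" prefix enforced.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

.normalize_consequence <- function(x) {
  x <- as.character(x)
  hit <- match(x, names(.consequence_synonyms))
  x[!is.na(hit)] <- .consequence_synonyms[hit[!is.na(hit)]]
  bad <- setdiff(unique(x), consequence_vocabulary())
  if (length(bad)) {
    stop("unknown consequence term(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(consequence_vocabulary(), collapse = ", "))
  }
  x
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("malformed file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read allele-specific copy-number segments
#'
#' Reads an ASCAT-style TSV with columns `sample`, `chrom`, `start`, `end`,
#' `major_cn`, `minor_cn` in 1-based inclusive coordinates and returns a
#' validated segment table in internal 0-based half-open coordinates with
#' `total_cn` filled in. Segments of one sample/chromosome must be
#' non-overlapping; they are returned sorted by sample, chromosome, start.
#'
#' @param path Path to the segments TSV.
#' @return A `data.frame` with columns `sample`, `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`, `total_cn`.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path, c("sample", "chrom", "start", "end",
                          "major_cn", "minor_cn"))
  if (nrow(df) == 0L) return(.empty_segments())
  seg <- data.frame(
    sample   = as.character(df$sample),
    chrom    = normalize_chrom(df$chrom),
    start    = as.numeric(df$start) - 1,  # 1-based incl -> 0-based half-open
    end      = as.numeric(df$end),
    major_cn = as.integer(df$major_cn),
    minor_cn = as.integer(df$minor_cn),
    stringsAsFactors = FALSE
  )
  validate_segments(seg, context = path)
  seg$total_cn <- seg$major_cn + seg$minor_cn
  sort_segments(seg)
}

.empty_segments <- function() {
  data.frame(sample = character(), chrom = character(),
             start = numeric(), end = numeric(),
             major_cn = integer(), minor_cn = integer(),
             total_cn = integer(), stringsAsFactors = FALSE)
}

#' Sort a segment table canonically
#' @param seg Segment `data.frame`.
#' @return The table ordered by sample, chromosome, start.
#' @export
sort_segments <- function(seg) {
  seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
}

#' Validate segment invariants
#'
#' Checks `end > start`, `minor_cn <= major_cn`, non-negative copy numbers and
#' non-overlap within each sample/chromosome, naming offending rows on error.
#'
#' @param seg Segment `data.frame` (internal coordinates).
#' @param context Label used in error messages (e.g. a file path).
#' @return Invisibly `TRUE`.
#' @export
validate_segments <- function(seg, context = "segments") {
  if (nrow(seg) == 0L) return(invisible(TRUE))
  bad <- which(!(seg$end > seg$start))
  if (length(bad)) stop(context, ": end <= start at row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(seg$minor_cn > seg$major_cn)
  if (length(bad)) stop(context, ": minor_cn > major_cn at row(s) ",
                        paste(bad, collapse = ", "))
  if (any(seg$major_cn < 0 | seg$minor_cn < 0)) {
    stop(context, ": negative copy number")
  }
  o <- order(seg$sample, seg$chrom, seg$start)
  s <- seg[o, , drop = FALSE]
  same <- s$sample[-1] == s$sample[-nrow(s)] & s$chrom[-1] == s$chrom[-nrow(s)]
  ovl <- which(same & s$start[-1] < s$end[-nrow(s)])
  if (length(ovl)) {
    rows <- sort(o[c(ovl, ovl + 1L)])
    stop(context, ": overlapping segments within sample/chromosome at row(s) ",
         paste(rows, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write segments to an ASCAT-style TSV
#'
#' Inverse of [read_segments()]: converts internal 0-based half-open
#' coordinates back to 1-based inclusive on disk.
#'
#' @param seg Segment `data.frame`.
#' @param path Output path.
#' @export
write_segments <- function(seg, path) {
  out <- data.frame(sample = seg$sample, chrom = seg$chrom,
                    start = format(seg$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(seg$end, scientific = FALSE, trim = TRUE),
                    major_cn = seg$major_cn, minor_cn = seg$minor_cn,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Orientation table for intrachromosomal rearrangements (our convention;
# low-end strand then high-end strand after canonical ordering):
#   +/-  deletion
#   -/+  tandem_duplication
#   +/+ or -/-  inversion
# Different chromosomes: translocation, regardless of strands.
.sv_class_from_orientation <- function(chrom1, strand1, chrom2, strand2) {
  ifelse(chrom1 != chrom2, "translocation",
    ifelse(strand1 == "+" & strand2 == "-", "deletion",
      ifelse(strand1 == "-" & strand2 == "+", "tandem_duplication",
             "inversion")))
}

#' Read rearrangement breakpoints from BEDPE
#'
#' Standard 10-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2`); the `name` column carries the sample identifier. Loci are
#' ordered canonically (chromosome then position) and the structural-variant
#' class is recomputed from the chromosome pair and strand combination using a
#' fixed orientation table (`+/-` deletion, `-/+` tandem duplication, equal
#' strands inversion, interchromosomal translocation); any class annotation in
#' the input is ignored.
#'
#' @param path Path to a BEDPE file (no header).
#' @return A `data.frame` with columns `sample`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `sv_class`, sorted canonically.
#' @export
read_breakpoints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  n0 <- length(readLines(path, n = 1L))
  if (n0 == 0L) return(.empty_breakpoints())
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop("malformed BEDPE ", path, ": fewer than 10 columns")
  bp <- data.frame(
    sample  = as.character(df[[7]]),
    chrom1  = normalize_chrom(df[[1]]),
    pos1    = as.numeric(df[[2]]),
    strand1 = as.character(df[[9]]),
    chrom2  = normalize_chrom(df[[4]]),
    pos2    = as.numeric(df[[5]]),
    strand2 = as.character(df[[10]]),
    stringsAsFactors = FALSE
  )
  if (any(!bp$strand1 %in% c("+", "-")) || any(!bp$strand2 %in% c("+", "-"))) {
    stop("malformed BEDPE ", path, ": strands must be '+' or '-'")
  }
  if (any(is.na(bp$pos1)) || any(is.na(bp$pos2)) ||
      any(bp$pos1 < 0) || any(bp$pos2 < 0)) {
    stop("malformed BEDPE ", path, ": invalid coordinates")
  }
  canonicalize_breakpoints(bp)
}

.empty_breakpoints <- function() {
  data.frame(sample = character(), chrom1 = character(), pos1 = numeric(),
             strand1 = character(), chrom2 = character(), pos2 = numeric(),
             strand2 = character(), sv_class = character(),
             stringsAsFactors = FALSE)
}

#' Canonically order breakpoint loci and assign SV classes
#' @param bp Breakpoint `data.frame` (without `sv_class`).
#' @return The table with loci swapped into (chrom, position) order,
#'   `sv_class` assigned, rows sorted.
#' @export
canonicalize_breakpoints <- function(bp) {
  if (nrow(bp)) {
    swap <- bp$chrom2 < bp$chrom1 |
      (bp$chrom2 == bp$chrom1 & bp$pos2 < bp$pos1)
    if (any(swap)) {
      tmp <- bp[swap, c("chrom1", "pos1", "strand1")]
      bp[swap, c("chrom1", "pos1", "strand1")] <-
        bp[swap, c("chrom2", "pos2", "strand2")]
      bp[swap, c("chrom2", "pos2", "strand2")] <- tmp
    }
  }
  bp$sv_class <- .sv_class_from_orientation(bp$chrom1, bp$strand1,
                                            bp$chrom2, bp$strand2)
  bp <- bp[order(bp$sample, bp$chrom1, bp$pos1, bp$chrom2, bp$pos2), ,
           drop = FALSE]
  rownames(bp) <- NULL
  bp
}

#' Write breakpoints as BEDPE
#' @param bp Breakpoint `data.frame` as returned by [read_breakpoints()].
#' @param path Output path.
#' @export
write_breakpoints <- function(bp, path) {
  if (nrow(bp) == 0L) {
    writeLines(character(), path)
    return(invisible(NULL))
  }
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- data.frame(bp$chrom1, fmt(bp$pos1), fmt(bp$pos1 + 1),
                    bp$chrom2, fmt(bp$pos2), fmt(bp$pos2 + 1),
                    bp$sample, ".", bp$strand1, bp$strand2,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read consequence-annotated point mutations
#'
#' TSV columns: `sample`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `consequence`, `gene` (may be empty). Common VEP-style consequence terms
#' are normalised through a synonym map; unknown terms raise an error listing
#' the allowed vocabulary. `variant_type` is derived from the allele lengths.
#'
#' @param path Path to the mutations TSV.
#' @return A `data.frame` with columns `sample`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `variant_type`, `consequence`, `gene`.
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path, c("sample", "chrom", "pos", "ref", "alt",
                          "consequence", "gene"))
  if (nrow(df) == 0L) {
    return(data.frame(sample = character(), chrom = character(),
                      pos = numeric(), ref = character(), alt = character(),
                      variant_type = character(), consequence = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  mut <- data.frame(
    sample = as.character(df$sample),
    chrom  = normalize_chrom(df$chrom),
    pos    = as.numeric(df$pos) - 1,
    ref    = as.character(df$ref),
    alt    = as.character(df$alt),
    stringsAsFactors = FALSE
  )
  mut$variant_type <- ifelse(nchar(mut$ref) != nchar(mut$alt),
                             "indel", "substitution")
  mut$consequence <- .normalize_consequence(df$consequence)
  mut$gene <- ifelse(is.na(df$gene), "", as.character(df$gene))
  mut[order(mut$sample, mut$chrom, mut$pos), , drop = FALSE]
}

#' Write point mutations to TSV
#' @param mut Mutation `data.frame` as returned by [read_mutations()].
#' @param path Output path.
#' @export
write_mutations <- function(mut, path) {
  out <- data.frame(sample = mut$sample, chrom = mut$chrom,
                    pos = format(mut$pos + 1, scientific = FALSE, trim = TRUE),
                    ref = mut$ref, alt = mut$alt,
                    consequence = mut$consequence, gene = mut$gene,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cancer-gene panel (BED + YAML roles/hotspots)
#'
#' The BED file (0-based half-open, columns chrom/start/end/gene) gives gene
#' footprints; the YAML config assigns each gene a role (`oncogene` or
#' `recessive`) and, for oncogenes, optional hotspots as `(position, alt)`
#' pairs (positions 1-based in the file, converted internally). Hotspots on
#' recessive genes are rejected.
#'
#' @param bed_path Path to the panel BED file.
#' @param config_path Path to the YAML role/hotspot config.
#' @return A `data.frame` with columns `gene`, `chrom`, `start`, `end`,
#'   `role`, and a list-column `hotspots` of data.frames with `pos`
#'   (0-based) and `alt`.
#' @export
read_gene_panel <- function(bed_path, config_path) {
  if (!file.exists(bed_path)) stop("file not found: ", bed_path)
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("panel BED needs >= 4 columns (chrom start end gene)")
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$genes)) stop("panel config must have a 'genes' mapping")
  panel <- data.frame(
    gene  = as.character(bed[[4]]),
    chrom = normalize_chrom(bed[[1]]),
    start = as.numeric(bed[[2]]),
    end   = as.numeric(bed[[3]]),
    stringsAsFactors = FALSE
  )
  roles <- character(nrow(panel))
  hotspots <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene[i]
    entry <- cfg$genes[[g]]
    if (is.null(entry) || is.null(entry$role)) {
      stop("panel config missing role for gene ", g)
    }
    if (!entry$role %in% c("oncogene", "recessive")) {
      stop("gene ", g, ": role must be 'oncogene' or 'recessive'")
    }
    roles[i] <- entry$role
    hs <- entry$hotspots
    if (length(hs)) {
      if (entry$role != "oncogene") {
        stop("gene ", g, ": hotspots are only meaningful for oncogenes")
      }
      hotspots[[i]] <- data.frame(
        pos = vapply(hs, function(h) as.numeric(h$position), numeric(1)) - 1,
        alt = vapply(hs, function(h) as.character(h$alt), character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      hotspots[[i]] <- data.frame(pos = numeric(), alt = character(),
                                  stringsAsFactors = FALSE)
    }
  }
  panel$role <- roles
  panel$hotspots <- hotspots
  if (anyDuplicated(panel$gene)) stop("duplicate gene symbols in panel BED")
  panel
}

#' Read a gene-level TPM expression matrix
#'
#' TSV with a `gene` column followed by one column per sample; all values must
#' be non-negative; gene and sample labels must be unique.
#'
#' @param path Path to the expression TSV.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path, "gene")
  genes <- as.character(df$gene)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(genes)) stop("duplicate gene labels in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels in ", path)
  if (any(is.na(m))) stop("missing TPM values in ", path)
  if (any(m < 0)) stop("negative TPM values in ", path)
  rownames(m) <- genes
  m
}

#' Write a TPM expression matrix to TSV
#' @param tpm Numeric matrix (genes x samples).
#' @param path Output path.
#' @export
write_expression <- function(tpm, path) {
  out <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
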