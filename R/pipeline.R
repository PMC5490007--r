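# End-to-end orchestration: load inputs, curate drivers, profile
# rearrangements, aggregate cohort copy number, find recurrent regions and
# run the expression-variance test, writing every result table to a run
# directory together with a config snapshot.

#' Run the full pipeline on files
#'
#' Reads segments, breakpoints, mutations, panel, expression and gene
#' annotation, then writes `drivers.tsv`, `profiles.tsv`, `genomes.tsv`,
#' `aggregate.tsv`, `regions.tsv`, `expr_test.tsv`, `report.tsv` (the
#' allele-specific target-gene report) and a `config.yaml` snapshot to
#' `out_dir`. Outputs are deterministic functions of the inputs.
#'
#' @param segments_path,breakpoints_path,mutations_path Input tables in the
#'   package's schemas.
#' @param panel_bed,panel_yaml Gene panel.
#' @param expression_path,genes_path Optional TPM matrix and gene annotation
#'   TSV (`gene`, `chrom`, `start`, `end`, 0-based); when absent the
#'   expression test is skipped.
#' @param out_dir Output directory (created).
#' @param chrom_lengths Named chromosome lengths for binning.
#' @param rules A [driver_rules()] object.
#' @param params A [chromothripsis_params()] object.
#' @param min_samples_recurrent Recurrence threshold for regions. Default 3.
#' @param bin_size Aggregation bin width. Default 1e6.
#' @return Invisibly, a list with all result objects.
#' @export
run_all <- function(segments_path, breakpoints_path, mutations_path,
                    panel_bed, panel_yaml,
                    expression_path = NULL, genes_path = NULL,
                    out_dir = ".",
                    chrom_lengths = grch37_chrom_lengths(),
                    rules = driver_rules(),
                    params = chromothripsis_params(),
                    min_samples_recurrent = 3L,
                    bin_size = 1e6) {
  for (p in c(segments_path, breakpoints_path, mutations_path, panel_bed,
              panel_yaml)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  segments <- read_segments(segments_path)
  breakpoints <- read_breakpoints(breakpoints_path)
  mutations <- read_mutations(mutations_path)
  panel <- read_gene_panel(panel_bed, panel_yaml)

  drivers <- curate_drivers(segments, breakpoints, mutations, panel, rules)
  prof <- profile_cohort(segments, breakpoints, rules, params)
  report <- allele_specific_report(panel, segments, breakpoints, rules)

  ploidies <- stats::setNames(
    ifelse(prof$genomes$ploidy_class == "tetraploid", 4, 2),
    prof$genomes$sample)
  chroms <- intersect(names(chrom_lengths), unique(segments$chrom))
  agg <- do.call(rbind, lapply(chroms, function(ch) {
    chromosome_aggregate(segments, ploidies, ch, chrom_lengths[[ch]],
                         bin_size)
  }))
  regions <- recurrent_ca_regions(prof$chromosomes, chrom_lengths,
                                  min_samples_recurrent, bin_size, panel)
  expr <- NULL
  if (!is.null(expression_path)) {
    tpm <- read_expression(expression_path)
    genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
    expr <- run_expression_test(prof$chromosomes, regions, tpm, genes)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(drivers, "drivers.tsv")
  wt(prof$chromosomes, "profiles.tsv")
  wt(prof$genomes, "genomes.tsv")
  wt(agg, "aggregate.tsv")
  wt(regions, "regions.tsv")
  wt(report, "report.tsv")
  if (!is.null(expr)) {
    if (!is.null(expr$regions)) wt(expr$regions, "expr_test.tsv")
    writeLines(c(paste("status:", expr$status),
                 if (!is.null(expr$result))
                   c(paste("n_regions_tested:", expr$result$n_regions_tested),
                     paste("k_ca_higher:", expr$result$k_ca_higher),
                     paste("p_value:", format(expr$result$p_value)))),
               file.path(out_dir, "expr_test_summary.txt"))
  }
  yaml::write_yaml(list(rules = unclass(rules), params = unclass(params),
                        min_samples_recurrent = min_samples_recurrent,
                        bin_size = bin_size),
                   file.path(out_dir, "config.yaml"))
  invisible(list(drivers = drivers, profiles = prof, report = report,
                 aggregate = agg, regions = regions, expression = expr))
}

#' One-command demo on a simulated cohort
#'
#' Simulates a cohort with [simulate_cohort()], runs the full pipeline on the
#' emitted files, and prints a truth-versus-called summary (genome classes,
#' planted versus recovered drivers, recurrent regions, expression test).
#'
#' @param out_dir Run directory.
#' @param seed Simulation seed.
#' @param config Optional [simulation_config()]; `seed` overrides its seed.
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a list with `truth`, `results` and `summary`.
#' @export
demo_run <- function(out_dir = tempfile("chromamp_demo"), seed = 1L,
                     config = NULL, quiet = FALSE) {
  if (is.null(config)) config <- simulation_config(seed = as.integer(seed))
  else config$seed <- as.integer(seed)
  sim_dir <- file.path(out_dir, "input")
  sim <- simulate_cohort(config, out_dir = sim_dir)
  res <- run_all(
    segments_path = file.path(sim_dir, "segments.tsv"),
    breakpoints_path = file.path(sim_dir, "breakpoints.bedpe"),
    mutations_path = file.path(sim_dir, "mutations.tsv"),
    panel_bed = system.file("extdata", "osteo_panel.bed",
                            package = "chromamp", mustWork = TRUE),
    panel_yaml = system.file("extdata", "osteo_panel.yaml",
                             package = "chromamp", mustWork = TRUE),
    expression_path = file.path(sim_dir, "expression.tsv"),
    genes_path = file.path(sim_dir, "genes.tsv"),
    out_dir = file.path(out_dir, "results"),
    chrom_lengths = config$chrom_lengths,
    rules = config$rules)

  truth <- sim$truth
  called <- res$profiles$genomes
  merged <- merge(truth$genomes, called, by = "sample",
                  suffixes = c("_planted", "_called"))
  class_acc <- mean(merged$class_planted == merged$class_called)
  planted_keys <- with(truth$drivers, paste(sample, gene, mechanism))
  called_keys <- with(res$drivers, paste(sample, gene, mechanism))
  summary <- list(
    n_samples = nrow(called),
    genome_class_accuracy = class_acc,
    drivers_planted = length(planted_keys),
    drivers_recovered = sum(planted_keys %in% called_keys),
    driver_false_positives = sum(!called_keys %in% planted_keys),
    n_recurrent_regions = nrow(res$regions),
    expression_p = if (!is.null(res$expression$result))
      res$expression$result$p_value else NA_real_)
  if (!quiet) {
    cat("samples:", summary$n_samples, "\n")
    cat("genome-class accuracy (planted vs called):",
        sprintf("%.1f%%", 100 * summary$genome_class_accuracy), "\n")
    cat("drivers recovered:", summary$drivers_recovered, "/",
        summary$drivers_planted, "; false positives:",
        summary$driver_false_positives, "\n")
    cat("recurrent CA regions:", summary$n_recurrent_regions, "\n")
    if (!is.na(summary$expression_p)) {
      cat("expression sign test: k =", res$expression$result$k_ca_higher,
          "/", res$expression$result$n_regions_tested,
          ", p =", format(summary$expression_p), "\n")
    }
  }
  invisible(list(truth = truth, results = res, summary = summary))
}
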