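Package: chromamp
Title: Driver Curation and Chromothripsis-Amplification Profiling of Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based curation of somatic driver mutations in cancer gene
    panels (hotspot point mutations, truncating events, focal amplifications,
    homozygous deletions, disruptive rearrangement breakpoints), classification
    of tumour genomes into quiet, chromothriptic and chromothripsis-amplified
    rearrangement profiles from allele-specific copy-number segments and
    structural-variant breakpoints, aggregate cohort copy-number profiling,
    allele-specific target-gene reporting, and a binomial sign test on the
    variance of TPM quartiles in recurrently chromothripsis-amplified regions.
    Includes a synthetic-cohort generator with planted rearrangement classes,
    driver events and dosage-coupled expression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
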