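Package: excapr
Title: Exon Capture Design and Cross-Species SNP Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing exome-subset capture experiments and
    discovering single-nucleotide variants across related species with a
    single annotated reference genome. Implements genome-wide exon target
    selection under a per-gene base-pair cap with a sequence-redundancy
    screen, filtering of mapped single-end reads (uniqueness, on-target
    overlap, PCR-duplicate removal by base-quality sum), empirical
    base-quality recalibration from per-quality mismatch rates with
    cross-sample averaging, Bayesian diploid consensus genotyping from
    pileups with depth and quality thresholds, and classification of calls
    into fixed differences versus heterozygous SNPs with the standard
    quality-control summaries (Ts/Tv ratios, known-variant concordance,
    Sanger verification). A fully seeded simulator generates annotated
    reference genomes, diverged diploid individuals with a known truth set,
    and capture reads, so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
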