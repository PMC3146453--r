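#' Run the capture SNP-discovery pipeline on a read set
#'
#' Convenience wrapper chaining the stages in the pipeline's canonical
#' order: uniqueness/on-target filtering, PCR-duplicate removal, optional
#' empirical base-quality recalibration (a table built from these reads,
#' or a supplied/averaged table), pileup construction over the targets,
#' diploid consensus calling, depth/quality thresholding, and variant
#' classification.
#'
#' @param reads An `excapr_reads` table (coordinate sorted).
#' @param targets GRanges of capture targets.
#' @param reference Named [Biostrings::DNAStringSet].
#' @param recalibrate `TRUE` to build a table from these reads and apply
#'   it; a `recal_table` to apply as given; `FALSE` to skip.
#' @param het_prior,hom_prior Genotype priors, see [call_consensus()].
#' @param min_depth,min_quality High-confidence thresholds, see
#'   [filter_calls()].
#' @param min_mapq Uniqueness threshold, see [filter_reads()].
#' @return List with `variants`, `calls` (high-confidence), `n_callable`,
#'   `filter_stats`, `dup_stats`, and `recal_table` (NULL when skipped).
#' @export
run_pipeline <- function(reads, targets, reference, recalibrate = TRUE,
                         het_prior = 0.001, hom_prior = het_prior,
                         min_depth = 8L, min_quality = 30L, min_mapq = 1L) {
  flt <- filter_reads(reads, targets, min_mapq = min_mapq)
  ded <- remove_pcr_duplicates(flt$reads)
  tab <- NULL
  rr <- ded$reads
  if (inherits(recalibrate, "recal_table")) {
    tab <- recalibrate
    rr <- apply_recalibration(rr, tab)
  } else if (isTRUE(recalibrate)) {
    tab <- build_recalibration_table(rr, reference)
    rr <- apply_recalibration(rr, tab)
  }
  pile <- build_pileup(rr, targets, reference)
  calls <- call_consensus(pile, het_prior = het_prior,
                          hom_prior = hom_prior)
  hc <- filter_calls(calls, min_depth = min_depth,
                     min_quality = min_quality)
  list(variants = classify_variants(hc$calls), calls = hc$calls,
       n_callable = hc$n_callable, filter_stats = flt$stats,
       dup_stats = ded$stats, recal_table = tab)
}
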