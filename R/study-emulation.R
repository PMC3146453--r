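#' End-to-end study emulation with known truth
#'
#' Runs the whole workflow under the package's reference study
#' conditions: a 1 Mb annotated genome (two chromosomes), a capture
#' design with complete exon sets for a small candidate-gene panel plus
#' genome-wide sampled genes under the per-gene cap, one diploid
#' individual diverged from the reference at 0.5% with per-site
#' heterozygosity 0.1%, and a 36 bp single-end library at 20x mean
#' on-target depth with 10% PCR duplicates and a Q30 error rate of 0.001.
#' Reads are filtered, duplicates removed, qualities recalibrated
#' empirically, genotypes called at each prior in `theta` (applied to
#' both the heterozygous and the non-reference homozygous prior mass),
#' thresholded at 8x / Q30, and classified. Results are compared with the
#' simulation truth restricted to callable positions, and call-set
#' stability across the prior sweep is measured.
#'
#' @param seed Integer master seed; every stage derives its own child
#'   seed from it.
#' @param divergence,heterozygosity Per-site rates for the simulated
#'   individual.
#' @param depth Mean on-target fold coverage.
#' @param duplicate_fraction PCR-duplicate fraction of the library.
#' @param error_rate True substitution error rate of the (all-Q30) base
#'   calls.
#' @param theta Genotype prior sweep; the first value is the primary
#'   call set.
#' @param chromosome_lengths,n_genes,n_candidate_genes,n_genomewide_genes,total_bp_budget
#'   Genome and design scale (defaults give roughly 60-70 kb of targets).
#' @return List: `summary` (one-row data.frame of the primary call set:
#'   counts, callable bases, percent), `truth_callable` (truth
#'   fixed/heterozygous counts at callable positions), `called`
#'   (fixed/het counts called), `tolerance_3sd` (3 binomial SDs for each
#'   class at the simulated rates), `overlap_percent` (shared calls
#'   across the theta sweep as a percent of the primary set),
#'   `dup_stats`, `filter_stats`, `recal_table`, `n_callable`.
#' @export
simulate_study <- function(seed = 1L,
                           divergence = 0.005, heterozygosity = 0.001,
                           depth = 20, duplicate_fraction = 0.10,
                           error_rate = 0.001,
                           theta = c(0.001, 0.004, 0.007),
                           chromosome_lengths = c(600000L, 400000L),
                           n_genes = 60L, n_candidate_genes = 10L,
                           n_genomewide_genes = 40L,
                           total_bp_budget = 100000) {
  genome <- generate_reference(genome_spec(
    chromosome_lengths, n_genes, n_candidate_genes = n_candidate_genes,
    seed = derive_seed(seed, "genome")))
  design <- design_targets(genome, design_config(
    n_genomewide_genes = n_genomewide_genes,
    total_bp_budget = total_bp_budget,
    candidate_gene_ids = genome$candidate_ids),
    seed = derive_seed(seed, "design"))
  ind <- derive_individual(genome, divergence, heterozygosity,
                           seed = derive_seed(seed, "individual"))
  reads <- simulate_reads(ind, design$targets, read_sim_spec(
    mean_on_target_depth = depth,
    duplicate_fraction = duplicate_fraction,
    per_quality_error = c("30" = error_rate),
    quality_dist = c("30" = 1),
    seed = derive_seed(seed, "reads")))

  flt <- filter_reads(reads, design$targets)
  ded <- remove_pcr_duplicates(flt$reads)
  tab <- build_recalibration_table(ded$reads, genome$seqs)
  recal <- apply_recalibration(ded$reads, tab)
  pile <- build_pileup(recal, design$targets, genome$seqs)

  callsets <- lapply(theta, function(th) {
    hc <- filter_calls(call_consensus(pile, het_prior = th,
                                      hom_prior = th))
    list(variants = classify_variants(hc$calls), calls = hc$calls,
         n_callable = hc$n_callable)
  })
  primary <- callsets[[1]]

  key <- function(x) paste(x$chrom, x$pos)
  truth <- ind$truth
  callable_keys <- key(primary$calls)
  truth_at_callable <- truth[key(truth) %in% callable_keys, ]
  truth_callable <- c(
    fixed = sum(truth_at_callable$class == "fixed"),
    heterozygous = sum(truth_at_callable$class == "heterozygous"))
  called <- c(
    fixed = sum(primary$variants$class == "fixed_difference"),
    heterozygous = sum(primary$variants$class == "heterozygous_snp"))
  n_callable <- primary$n_callable
  tolerance_3sd <- c(
    fixed = 3 * sqrt(n_callable * divergence * (1 - divergence)),
    heterozygous = 3 * sqrt(n_callable * heterozygosity *
                              (1 - heterozygosity)))

  overlap <- callset_overlap(lapply(callsets, `[[`, "variants"))

  list(summary = summarize_variants(primary$variants, n_callable),
       truth_callable = truth_callable, called = called,
       tolerance_3sd = tolerance_3sd,
       overlap_percent = overlap$percent_of_first,
       n_callable = n_callable,
       dup_stats = ded$stats, filter_stats = flt$stats,
       recal_table = tab,
       design_total_bp = design$total_bp)
}
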