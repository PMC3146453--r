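#' Classify high-confidence calls into variants
#'
#' Calls homozygous for the reference base are dropped; single-base calls
#' differing from the reference become fixed differences and
#' ambiguity-code calls become heterozygous SNPs (including the rare
#' heterozygote with neither allele equal to the reference). Calls with a
#' genotype outside the ten diploid IUPAC codes are skipped with a
#' warning.
#'
#' @param calls High-confidence `excapr_calls` (after [filter_calls()]).
#' @return A data.frame of class `excapr_variants`: chrom, pos (1-based),
#'   ref, genotype, class (`"fixed_difference"` or `"heterozygous_snp"`),
#'   depth, qual.
#' @export
classify_variants <- function(calls) {
  gt <- toupper(calls$genotype)
  valid <- gt %in% names(IUPAC_ALLELES)
  if (any(!valid)) {
    warning(sum(!valid), " call(s) with non-ACGT genotype skipped")
    calls <- calls[valid, , drop = FALSE]
    gt <- gt[valid]
  }
  het <- is_het_code(gt)
  keep <- het | gt != toupper(calls$ref)
  out <- data.frame(
    chrom = calls$chrom[keep], pos = calls$pos[keep],
    ref = toupper(calls$ref[keep]), genotype = gt[keep],
    class = ifelse(het[keep], "heterozygous_snp", "fixed_difference"),
    depth = calls$depth[keep], qual = calls$qual[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("excapr_variants", "data.frame")
  out
}

#' Variant summary statistics
#'
#' Heterozygous and fixed counts, their total, and the total as a
#' percentage of genotyped (callable) bases, rounded half-up to two
#' decimals. When a known-variant table is supplied, position matches,
#' the match percentage (of all variants) and allele mismatches are
#' appended (see [dbsnp_concordance()]).
#'
#' @param variants An `excapr_variants` data.frame.
#' @param n_genotyped_bases Number of high-confidence genotyped positions
#'   (must be positive).
#' @param known Optional known-variant table for concordance columns.
#' @return One-row data.frame: n_heterozygous, n_fixed, n_total,
#'   n_genotyped_bases, percent_total, and (when `known` is given)
#'   dbsnp_position_matches, dbsnp_match_percent, dbsnp_allele_mismatches.
#' @export
summarize_variants <- function(variants, n_genotyped_bases, known = NULL) {
  if (n_genotyped_bases <= 0) stop("n_genotyped_bases must be positive")
  n_het <- sum(variants$class == "heterozygous_snp")
  n_fix <- sum(variants$class == "fixed_difference")
  out <- data.frame(
    n_heterozygous = n_het, n_fixed = n_fix, n_total = n_het + n_fix,
    n_genotyped_bases = n_genotyped_bases,
    percent_total = round_half_up(100 * (n_het + n_fix) /
                                    n_genotyped_bases, 2))
  if (!is.null(known)) {
    cc <- dbsnp_concordance(variants, known)
    out$dbsnp_position_matches <- cc$position_matches
    out$dbsnp_match_percent <- cc$match_percent
    out$dbsnp_allele_mismatches <- cc$allele_mismatches
  }
  out
}

#' Variant summary from pre-tabulated counts
#'
#' The same arithmetic as [summarize_variants()] but starting from counts
#' (heterozygous, fixed, genotyped bases, and optionally known-variant
#' position matches and allele mismatches), for summarising call sets
#' tabulated elsewhere. All percentages are rounded half-up to two
#' decimals.
#'
#' @param n_heterozygous,n_fixed,n_genotyped_bases Counts.
#' @param dbsnp_position_matches,dbsnp_allele_mismatches Optional
#'   known-variant concordance counts.
#' @return One-row data.frame in the [summarize_variants()] layout.
#' @export
summarize_counts <- function(n_heterozygous, n_fixed, n_genotyped_bases,
                             dbsnp_position_matches = NULL,
                             dbsnp_allele_mismatches = NULL) {
  if (n_genotyped_bases <= 0) stop("n_genotyped_bases must be positive")
  n_total <- n_heterozygous + n_fixed
  out <- data.frame(
    n_heterozygous = n_heterozygous, n_fixed = n_fixed, n_total = n_total,
    n_genotyped_bases = n_genotyped_bases,
    percent_total = round_half_up(100 * n_total / n_genotyped_bases, 2))
  if (!is.null(dbsnp_position_matches)) {
    out$dbsnp_position_matches <- dbsnp_position_matches
    out$dbsnp_match_percent <-
      round_half_up(100 * dbsnp_position_matches / n_total, 2)
    out$dbsnp_allele_mismatches <- dbsnp_allele_mismatches %||% NA_integer_
  }
  out
}

#' Path to the packaged per-individual variant count fixture
#'
#' Published per-individual counts (heterozygous SNPs, fixed differences,
#' genotyped bases, dbSNP position matches and allele mismatches) for the
#' bison, zebu and taurine individuals, used as inputs to the summary
#' arithmetic.
#'
#' @return File path inside the installed package.
#' @export
variant_counts_fixture_path <- function() {
  system.file("extdata", "variant_summary_counts.tsv", package = "excapr",
              mustWork = TRUE)
}

#' Concordance with a known-variant (dbSNP-like) table
#'
#' A position match is a called variant at a known-variant position (same
#' chromosome and 1-based position — no coordinate-system heuristics are
#' applied, supply both in the same convention). An allele mismatch is a
#' position match whose genotype allele set is disjoint from the known
#' allele set. The match percentage is position matches over all called
#' variants, rounded half-up to two decimals.
#'
#' @param variants An `excapr_variants` data.frame.
#' @param known Data.frame with columns chrom, pos and alleles
#'   (comma-separated string, e.g. `"A,G"`), e.g. from
#'   [read_known_variants()].
#' @return One-row data.frame: position_matches, allele_mismatches,
#'   match_percent.
#' @export
dbsnp_concordance <- function(variants, known) {
  if (nrow(variants) == 0 || nrow(known) == 0)
    return(data.frame(position_matches = 0L, allele_mismatches = 0L,
                      match_percent = if (nrow(variants)) 0 else NA_real_))
  vkey <- paste(variants$chrom, variants$pos)
  kkey <- paste(known$chrom, known$pos)
  m <- match(vkey, kkey)
  hit <- !is.na(m)
  n_match <- sum(hit)
  n_mismatch <- 0L
  if (n_match > 0) {
    va <- iupac_to_alleles(variants$genotype[hit])
    ka <- strsplit(toupper(known$alleles[m[hit]]), ",", fixed = TRUE)
    disjoint <- vapply(seq_len(n_match), function(i)
      !any(c(va[i, 1], va[i, 2]) %in% ka[[i]]), TRUE)
    n_mismatch <- sum(disjoint)
  }
  data.frame(position_matches = n_match, allele_mismatches = n_mismatch,
             match_percent = round_half_up(100 * n_match /
                                             nrow(variants), 2))
}

#' Read a known-variant table (TSV or VCF)
#'
#' TSV input needs three columns: chrom, pos (1-based) and alleles
#' (comma-separated). VCF input takes REF and ALT as the allele set.
#'
#' @param path Input file; `.vcf` extension selects VCF parsing.
#' @return Data.frame with chrom, pos, alleles.
#' @export
read_known_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    return(data.frame(
      chrom = vapply(f, `[`, "", 1),
      pos = as.integer(vapply(f, `[`, "", 2)),
      alleles = paste(vapply(f, `[`, "", 4), vapply(f, `[`, "", 5),
                      sep = ","),
      stringsAsFactors = FALSE))
  }
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "alleles") %in% names(out)))
  out
}

TRANSITIONS <- c("A" = "G", "G" = "A", "C" = "T", "T" = "C")

#' Transition/transversion ratio of heterozygous SNPs
#'
#' Each heterozygote contributes its reference-to-alternate substitution
#' type: for a heterozygote carrying the reference allele, the non-
#' reference allele defines the substitution; a heterozygote with two
#' non-reference alleles contributes both ref-to-alt substitutions at half
#' weight. Transitions are A<->G and C<->T.
#'
#' @param het_variants `excapr_variants` rows of class heterozygous_snp
#'   (rows of other classes are ignored).
#' @return Ratio transitions/transversions, or `NA` when there are no
#'   transversions.
#' @export
titv_ratio <- function(het_variants) {
  v <- het_variants[het_variants$class == "heterozygous_snp", , drop = FALSE]
  if (nrow(v) == 0) return(NA_real_)
  al <- iupac_to_alleles(v$genotype)
  ts <- 0; tv <- 0
  for (i in seq_len(nrow(v))) {
    ref <- v$ref[i]
    alts <- setdiff(c(al[i, 1], al[i, 2]), ref)
    w <- 1 / length(alts)
    for (a in alts) {
      if (TRANSITIONS[[ref]] == a) ts <- ts + w else tv <- tv + w
    }
  }
  if (tv == 0) return(NA_real_)
  ts / tv
}

#' Per-gene heterozygous SNP counts
#'
#' Assigns each variant to the target exon containing it and, through it,
#' to a gene; variants outside all targets are tallied in an `off_target`
#' bucket with a warning. Aggregates over the candidate-gene list are
#' returned alongside the per-gene table.
#'
#' @param variants An `excapr_variants` data.frame.
#' @param targets GRanges of targets with a `gene_id` column.
#' @param candidate_ids Character vector of candidate gene ids.
#' @return List with `per_gene` (gene_id, n_het, n_fixed, n_total; an
#'   `off_target` row when applicable), `n_candidate_genes_hit` (candidate
#'   genes with at least one het SNP) and `n_het_in_candidates`.
#' @export
per_gene_counts <- function(variants, targets, candidate_ids = character(0)) {
  if (nrow(variants) == 0) {
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_het = integer(0),
                                      n_fixed = integer(0),
                                      n_total = integer(0)),
                n_candidate_genes_hit = 0L, n_het_in_candidates = 0L))
  }
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(vr, targets, ignore.strand = TRUE,
                                    select = "first")
  gene <- ifelse(is.na(ov), "off_target",
                 S4Vectors::mcols(targets)$gene_id[ov])
  if (any(is.na(ov)))
    warning(sum(is.na(ov)), " variant(s) outside all targets counted ",
            "under 'off_target'")
  dt <- data.table::data.table(gene_id = gene,
                               het = variants$class == "heterozygous_snp")
  per_gene <- dt[, .(n_het = sum(het), n_fixed = sum(!het),
                     n_total = .N), by = "gene_id"]
  data.table::setorderv(per_gene, "gene_id")
  in_cand <- per_gene$gene_id %in% candidate_ids
  list(per_gene = as.data.frame(per_gene),
       n_candidate_genes_hit = sum(in_cand & per_gene$n_het > 0),
       n_het_in_candidates = sum(per_gene$n_het[in_cand]))
}

#' Compare pipeline variant calls with Sanger verification genotypes
#'
#' For each verification record (a position inside a Sanger-resequenced
#' window, with the Sanger genotype and the pipeline genotype as IUPAC
#' codes): a record is concordant when the pipeline genotype equals the
#' Sanger genotype (case-insensitive) and is a variant relative to the
#' reference; it is a false positive when the pipeline called a variant
#' but the Sanger genotype equals the reference base.
#'
#' @param records Data.frame with columns sample, position, reference,
#'   sanger and a pipeline-genotype column (`pipeline_col`). The packaged
#'   verification fixture ([sanger_fixture_path()]) uses column `maq`.
#' @param pipeline_col Name of the pipeline-genotype column.
#' @return List with `by_sample` (sample, n_records, concordant,
#'   false_positives) and `discordant` (the non-concordant records).
#' @export
compare_to_sanger <- function(records, pipeline_col = "maq") {
  stopifnot(all(c("sample", "reference", "sanger", pipeline_col)
                %in% names(records)))
  pg <- toupper(records[[pipeline_col]])
  sg <- toupper(records$sanger)
  ref <- toupper(records$reference)
  ok <- c(pg, sg) %in% names(IUPAC_ALLELES)
  if (!all(ok)) stop("malformed IUPAC genotype in verification records")
  concord <- pg == sg & pg != ref
  fp <- pg != ref & sg == ref
  dt <- data.table::data.table(sample = records$sample,
                               concord = concord, fp = fp)
  by_sample <- dt[, .(n_records = .N, concordant = sum(concord),
                      false_positives = sum(fp)), by = "sample"]
  list(by_sample = as.data.frame(by_sample),
       discordant = records[!concord, , drop = FALSE])
}

#' Overlap of variant call sets
#'
#' Call identity is (chrom, pos, genotype). Reports the number of calls
#' shared by all sets, that number as a fraction of the first set
#' (rounded to a whole percent), and the pairwise intersection-size
#' matrix. Used to probe call-set stability across genotyping prior
#' settings.
#'
#' @param callsets List of `excapr_variants` (or calls) data.frames.
#' @return List with `n_shared_all`, `percent_of_first`,
#'   `pairwise` (matrix of intersection sizes).
#' @export
callset_overlap <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  keys <- lapply(callsets, function(v)
    unique(paste(v$chrom, v$pos, toupper(v$genotype))))
  shared <- Reduce(intersect, keys)
  k <- length(callsets)
  pw <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  list(n_shared_all = length(shared),
       percent_of_first = round_half_up(100 * length(shared) /
                                          max(length(keys[[1]]), 1L)),
       pairwise = pw)
}

#' Per-chromosome variant counts
#'
#' Counts of all differences and of heterozygous SNPs per chromosome;
#' the column sums equal the variant-summary totals.
#'
#' @param variants An `excapr_variants` data.frame.
#' @param chromosomes Character vector of valid chromosome names.
#' @return Data.frame: chrom, n_total, n_het, n_fixed (one row per
#'   chromosome in `chromosomes`, zero-filled).
#' @export
chromosome_distribution <- function(variants, chromosomes) {
  if (!all(variants$chrom %in% chromosomes))
    stop("variant on unknown chromosome: ",
         paste(setdiff(unique(variants$chrom), chromosomes), collapse = ", "))
  dt <- data.table::data.table(
    chrom = factor(variants$chrom, levels = chromosomes),
    het = variants$class == "heterozygous_snp")
  out <- dt[, .(n_total = .N, n_het = sum(het), n_fixed = sum(!het)),
            by = "chrom"]
  full <- data.table::data.table(chrom = factor(chromosomes,
                                                levels = chromosomes))
  out <- out[full, on = "chrom"]
  for (cn in c("n_total", "n_het", "n_fixed"))
    data.table::set(out, which(is.na(out[[cn]])), cn, 0L)
  out <- as.data.frame(out)
  out$chrom <- as.character(out$chrom)
  out
}

#' Path to the packaged Sanger verification fixture
#'
#' A TSV with the Sanger-resequencing verification records for the three
#' study individuals (columns sample, chrom, sanger_start, sanger_stop,
#' position, reference, sanger, maq, gene).
#'
#' @return File path inside the installed package.
#' @export
sanger_fixture_path <- function() {
  system.file("extdata", "sanger_verification.tsv", package = "excapr",
              mustWork = TRUE)
}

#' Read a Sanger verification table
#'
#' @param path TSV with the columns described in [compare_to_sanger()].
#' @return Data.frame of verification records; positions are checked to
#'   lie within their Sanger windows.
#' @export
read_sanger_table <- function(path = sanger_fixture_path()) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (all(c("sanger_start", "sanger_stop", "position") %in% names(out)) &&
      !all(out$position >= out$sanger_start &
           out$position <= out$sanger_stop))
    stop("verification record position outside its Sanger window")
  out
}
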