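#' Derive a diverged diploid individual from a reference genome
#'
#' Introduces homozygous substitutions ("fixed differences" relative to the
#' reference) at an expected per-site rate of `divergence_rate` and
#' heterozygous substitutions at `heterozygosity_rate`. Edited sites are
#' sampled without replacement so a site is never both fixed and
#' heterozygous. Every heterozygous edit places the alternate allele on
#' exactly one of the two haplotypes (chosen at random). The exact set of
#' edits is returned as a truth table for downstream parameter-recovery
#' tests.
#'
#' @param genome An `excapr_genome` from [generate_reference()].
#' @param divergence_rate Expected homozygous substitutions per site, in
#'   `[0, 0.05]`. A rate of 0.005 emulates a wild congener diverged by one
#'   to two million years from the reference species; 0.002 a conspecific
#'   breed or subspecies.
#' @param heterozygosity_rate Expected heterozygous sites per site, in
#'   `[0, 0.05]`; around 0.001 for outbred mammals.
#' @param seed Integer seed.
#' @return An object of class `excapr_individual`: list with `haplotypes`
#'   (list of two named DNAStringSets, `h1` and `h2`), `truth` (data.frame
#'   with chrom, pos (1-based), ref, genotype as IUPAC code, class one of
#'   `"fixed"`/`"heterozygous"`), and the rates used.
#' @export
derive_individual <- function(genome, divergence_rate = 0.005,
                              heterozygosity_rate = 0.001, seed = 1L) {
  stopifnot(inherits(genome, "excapr_genome"))
  if (divergence_rate < 0 || divergence_rate > 0.05 ||
      heterozygosity_rate < 0 || heterozygosity_rate > 0.05)
    stop("rates must lie in [0, 0.05]")
  if (divergence_rate + heterozygosity_rate > 0.1)
    stop("divergence_rate + heterozygosity_rate above 0.1 rejected")
  set.seed(derive_seed(seed, "individual"))

  h1 <- genome$seqs
  h2 <- genome$seqs
  truth <- list()
  for (ci in seq_along(genome$seqs)) {
    chrom <- names(genome$seqs)[ci]
    L <- length(genome$seqs[[ci]])
    n_fix <- rbinom(1L, L, divergence_rate)
    n_het <- rbinom(1L, L, heterozygosity_rate)
    if (n_fix + n_het == 0L) next
    pos <- sample.int(L, n_fix + n_het)          # disjoint by construction
    fix_pos <- sort(pos[seq_len(n_fix)])
    het_pos <- sort(pos[n_fix + seq_len(n_het)])
    chars <- strsplit(as.character(genome$seqs[[ci]]), "")[[1]]
    ref_fix <- chars[fix_pos]
    ref_het <- chars[het_pos]
    alt_of <- function(ref) {
      vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    }
    alt_fix <- alt_of(ref_fix)
    alt_het <- alt_of(ref_het)
    het_hap <- sample(c(1L, 2L), n_het, replace = TRUE)

    if (n_fix > 0) {
      h1[[ci]] <- Biostrings::replaceLetterAt(h1[[ci]], fix_pos, alt_fix)
      h2[[ci]] <- Biostrings::replaceLetterAt(h2[[ci]], fix_pos, alt_fix)
    }
    if (n_het > 0) {
      on1 <- het_hap == 1L
      if (any(on1))
        h1[[ci]] <- Biostrings::replaceLetterAt(h1[[ci]], het_pos[on1],
                                                alt_het[on1])
      if (any(!on1))
        h2[[ci]] <- Biostrings::replaceLetterAt(h2[[ci]], het_pos[!on1],
                                                alt_het[!on1])
    }
    truth[[chrom]] <- data.frame(
      chrom = chrom,
      pos = c(fix_pos, het_pos),
      ref = c(ref_fix, ref_het),
      genotype = c(alt_fix,
                   if (n_het > 0) genotype_to_iupac(ref_het, alt_het)
                   else character(0)),
      class = rep(c("fixed", "heterozygous"), c(n_fix, n_het)),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               genotype = character(0), class = character(0))
  rownames(truth) <- NULL
  truth <- truth[order(match(truth$chrom, names(genome$seqs)), truth$pos), ]
  rownames(truth) <- NULL

  structure(list(haplotypes = list(h1 = h1, h2 = h2), truth = truth,
                 divergence_rate = divergence_rate,
                 heterozygosity_rate = heterozygosity_rate),
            class = "excapr_individual")
}

#' Write a truth set as TSV
#'
#' Columns: chrom, pos (1-based), ref, genotype (IUPAC), class.
#'
#' @param truth The `truth` data.frame of an `excapr_individual`.
#' @param path Output file.
#' @export
write_truth_set <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
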