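# the 10 unordered diploid genotypes over A/C/G/T, alphabetical
GENOTYPES <- local({
  b <- c("A", "C", "G", "T")
  idx <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  g <- data.frame(a1 = b[idx[, 1]], a2 = b[idx[, 2]])
  g[order(g$a1, g$a2), , drop = FALSE]
})
rownames(GENOTYPES) <- NULL

#' Build a pileup over targeted positions
#'
#' One column per targeted reference position covered by at least one
#' read; each aligned read contributes the base and quality at the offset
#' aligned to the position. Reads with indel-containing CIGARs are skipped
#' with a warning; non-ACGT read bases and reference-N positions are
#' dropped.
#'
#' @param reads Filtered, duplicate-free `excapr_reads` (coordinate
#'   sorted).
#' @param targets GRanges of capture targets.
#' @param reference Named [Biostrings::DNAStringSet].
#' @return A `data.table` of class `excapr_pileup` with columns chrom,
#'   pos (1-based), ref, base, qual (integer Phred), strand, grouped by
#'   (chrom, pos).
#' @export
build_pileup <- function(reads, targets, reference) {
  bases <- expand_read_bases(reads)
  chrom_len <- setNames(Biostrings::width(reference), names(reference))
  keep <- rep(FALSE, nrow(bases))
  t_chrom <- as.character(GenomicRanges::seqnames(targets))
  for (cn in unique(bases$chrom)) {
    if (!cn %in% names(chrom_len))
      stop("read chromosome ", cn, " absent from the reference")
    mask <- rep(FALSE, chrom_len[[cn]])
    sel <- t_chrom == cn
    if (any(sel)) {
      st <- GenomicRanges::start(targets)[sel]
      en <- GenomicRanges::end(targets)[sel]
      for (i in seq_along(st))
        mask[st[i]:en[i]] <- TRUE
    }
    idx <- bases$chrom == cn
    keep[idx] <- mask[bases$pos[idx]]
  }
  bases <- bases[keep & code > 0L]
  refc <- reference_codes(reference)
  if (nrow(bases) > 0)
    bases[, ref_code := refc[[chrom[1]]][pos], by = "chrom"]
  else bases[, ref_code := integer(0)]
  bases <- bases[ref_code > 0L]
  out <- bases[, .(chrom, pos, ref = DNA_BASES[ref_code],
                   base = DNA_BASES[code], qual, strand)]
  data.table::setorderv(out, c("chrom", "pos"))
  data.table::setattr(out, "class", c("excapr_pileup", class(out)))
  out[]
}

#' Call diploid consensus genotypes from a pileup
#'
#' Bayesian diploid caller: for each covered position the posterior is
#' computed over the 10 unordered genotypes `{x,y}`, treating base calls
#' as independent draws with `P(b | {x,y}) = (p(b|x) + p(b|y)) / 2` and
#' `p(b|x) = 1 - e` when `b = x`, else `e/3`, where `e = 10^(-q/10)` from
#' the (recalibrated) base quality. The prior puts mass
#' `1 - het_prior - hom_prior` on the reference homozygote, `het_prior/3`
#' on each heterozygote containing the reference allele, and `hom_prior/6`
#' on each of the six remaining genotypes. The consensus quality is
#' `round(-10*log10(1 - posterior))` of the winning genotype, capped at
#' 99; ties are broken toward a genotype containing the reference allele,
#' then alphabetically.
#'
#' @param pileup An `excapr_pileup`.
#' @param het_prior Prior probability that a site is heterozygous with the
#'   reference allele (default 0.001, the conventional per-site
#'   heterozygosity scale; sweep it to probe call-set stability).
#' @param hom_prior Prior mass on the six genotypes without the reference
#'   allele (defaults to `het_prior`; at cross-species divergence the
#'   fixed-difference rate is of the same order as heterozygosity).
#' @return A data.frame of class `excapr_calls`: chrom, pos (1-based),
#'   ref, genotype (IUPAC single letter), qual, depth.
#' @export
call_consensus <- function(pileup, het_prior = 0.001,
                           hom_prior = het_prior) {
  stopifnot(het_prior > 0, hom_prior > 0, het_prior + hom_prior < 1)
  if (nrow(pileup) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), genotype = character(0),
                      qual = integer(0), depth = integer(0))
    class(out) <- c("excapr_calls", "data.frame")
    return(out)
  }
  dt <- data.table::as.data.table(pileup)
  dt[, sid := .GRP, by = c("chrom", "pos")]
  sites <- dt[, .(chrom = chrom[1], pos = pos[1], ref = ref[1],
                  depth = .N), by = "sid"]
  e <- phred_to_error(dt$qual)
  b <- dt$base
  n_sites <- nrow(sites)

  ll <- matrix(0, n_sites, 10L)
  for (g in seq_len(10L)) {
    x <- GENOTYPES$a1[g]; y <- GENOTYPES$a2[g]
    px <- ifelse(b == x, 1 - e, e / 3)
    py <- ifelse(b == y, 1 - e, e / 3)
    ll[, g] <- rowsum(log((px + py) / 2), dt$sid)[, 1]
  }

  contains_ref <- outer(sites$ref, seq_len(10L), function(r, g)
    GENOTYPES$a1[g] == r | GENOTYPES$a2[g] == r)
  is_hom <- GENOTYPES$a1 == GENOTYPES$a2
  is_ref_hom <- outer(sites$ref, seq_len(10L), function(r, g)
    is_hom[g] & GENOTYPES$a1[g] == r)
  log_prior <- matrix(log(hom_prior / 6), n_sites, 10L)
  log_prior[contains_ref & !is_ref_hom] <- log(het_prior / 3)
  log_prior[is_ref_hom] <- log(1 - het_prior - hom_prior)

  post <- ll + log_prior
  bv <- do.call(pmax, as.data.frame(post))
  rel <- exp(post - bv)
  sumexp <- rowSums(rel)
  # tie-break: highest posterior, then ref-containing, then alphabetical
  tie <- rel >= 1 - 1e-9
  pref <- matrix(rep((10 - seq_len(10L)) * 0.01, each = n_sites),
                 n_sites, 10L)
  score <- tie * (1 + 10 * contains_ref + pref)
  win <- max.col(score, ties.method = "first")
  p_others <- (sumexp - rel[cbind(seq_len(n_sites), win)]) / sumexp
  qual <- pmin(ifelse(p_others <= 0, 99,
                      round_half_up(-10 * log10(p_others))), 99)

  out <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
    genotype = genotype_to_iupac(GENOTYPES$a1[win], GENOTYPES$a2[win]),
    qual = as.integer(qual), depth = sites$depth,
    stringsAsFactors = FALSE)
  class(out) <- c("excapr_calls", "data.frame")
  out
}

#' Threshold consensus calls to the high-confidence set
#'
#' Retains calls with depth of at least `min_depth` and consensus quality
#' of at least `min_quality`; the number retained is the callable-base
#' count (the denominator for genome-wide variant percentages).
#'
#' @param calls An `excapr_calls` data.frame.
#' @param min_depth Minimum depth (default 8).
#' @param min_quality Minimum consensus quality (default 30).
#' @return List with `calls` (the retained calls) and `n_callable`.
#' @export
filter_calls <- function(calls, min_depth = 8L, min_quality = 30L) {
  stopifnot(min_depth >= 0, min_quality >= 0)
  keep <- calls$depth >= min_depth & calls$qual >= min_quality
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(calls)
  list(calls = out, n_callable = nrow(out))
}
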