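suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# small genome + design used by several pipeline tests
small_genome <- function(seed = 7, lens = c(100000L, 50000L),
                         n_genes = 30L, n_candidate = 4L) {
  generate_reference(genome_spec(lens, n_genes,
                                 n_candidate_genes = n_candidate,
                                 seed = seed))
}

small_design <- function(genome, n_gw = 15L, budget = 40000, seed = 11) {
  design_targets(genome,
                 design_config(n_genomewide_genes = n_gw,
                               total_bp_budget = budget,
                               candidate_gene_ids = genome$candidate_ids),
                 seed = seed)
}

# hand-built read table (coordinate sorted unless asked otherwise)
make_reads <- function(chrom, pos, strand = "+", seq = NULL, qual = NULL,
                       mapq = 60L, read_id = NULL, L = 36L) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n); mapq <- rep_len(as.integer(mapq), n)
  if (is.null(seq)) seq <- strrep("A", L)
  if (is.null(qual)) qual <- strrep("I", L)         # Q40
  seq <- rep_len(seq, n); qual <- rep_len(qual, n)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  rd <- data.table::data.table(
    read_id = read_id, chrom = chrom, pos = pos, strand = strand,
    mapq = mapq, cigar = paste0(nchar(seq), "M"), seq = seq, qual = qual)
  data.table::setorderv(rd, c("chrom", "pos", "read_id"))
  data.table::setattr(rd, "class", c("excapr_reads", class(rd)))
  rd[]
}

# pileup column builder: one site, given observed bases and quals
make_pileup <- function(ref, bases, quals, chrom = "chr1", pos = 100L) {
  p <- data.table::data.table(
    chrom = chrom, pos = as.integer(pos), ref = ref, base = bases,
    qual = as.integer(quals), strand = "+")
  data.table::setattr(p, "class", c("excapr_pileup", class(p)))
  p[]
}

variant_df <- function(chrom, pos, ref, genotype) {
  het <- genotype %in% c("M", "R", "W", "S", "Y", "K")
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    genotype = genotype,
                    class = ifelse(het, "heterozygous_snp",
                                   "fixed_difference"),
                    depth = 20L, qual = 60L, stringsAsFactors = FALSE)
  class(out) <- c("excapr_variants", "data.frame")
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# independent brute-force window-identity oracle used against the
# seed-and-extend redundancy screen: slides every ungapped offset of a
# against b and counts matches in every window of exactly `window` bp
oracle_best_window_matches <- function(a, b, window = 40L) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (d in (-(nb - 1)):(na - 1)) {
    lo <- max(1L, 1L + d); hi <- min(na, nb + d)
    if (hi - lo + 1L < window) next
    m <- av[lo:hi] == bv[(lo - d):(hi - d)] &
      av[lo:hi] %in% c("A", "C", "G", "T")
    cs <- cumsum(as.integer(m))
    len <- length(m)
    w <- cs[window:len] - c(0L, cs[seq_len(len - window)])
    best <- max(best, max(w))
  }
  best
}

oracle_redundant <- function(cand, collected, window = 40L,
                             identity = 0.9) {
  thr <- floor(identity * window + 1e-9) + 1L
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (s in collected) {
    if (nchar(s) < window || nchar(cand) < window) next
    if (oracle_best_window_matches(cand, s, window) >= thr) return(TRUE)
    if (oracle_best_window_matches(rc(cand), s, window) >= thr) return(TRUE)
  }
  FALSE
}

# independent exhaustive posterior enumeration over the 10 diploid
# genotypes, plain probability arithmetic (no logs)
oracle_call <- function(ref, bases, quals, het_prior = 0.001,
                        hom_prior = het_prior) {
  B <- c("A", "C", "G", "T")
  gts <- list()
  for (i in 1:4) for (j in i:4) gts[[length(gts) + 1]] <- c(B[i], B[j])
  e <- 10^(-quals / 10)
  post <- vapply(gts, function(g) {
    lik <- 1
    for (k in seq_along(bases)) {
      px <- if (bases[k] == g[1]) 1 - e[k] else e[k] / 3
      py <- if (bases[k] == g[2]) 1 - e[k] else e[k] / 3
      lik <- lik * (px + py) / 2
    }
    prior <- if (g[1] == ref && g[2] == ref) 1 - het_prior - hom_prior
    else if (g[1] == ref || g[2] == ref) het_prior / 3
    else hom_prior / 6
    lik * prior
  }, 0)
  post <- post / sum(post)
  contains_ref <- vapply(gts, function(g) ref %in% g, TRUE)
  ord <- order(-post, !contains_ref, seq_along(gts))
  best <- ord[1]
  q <- min(floor(-10 * log10(max(1 - post[best], 1e-300)) + 0.5), 99)
  list(genotype = genotype_to_iupac(gts[[best]][1], gts[[best]][2]),
       qual = as.integer(q), posterior = post[best])
}
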