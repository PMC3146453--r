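#' Specification for simulated capture reads
#'
#' Parameters of a simulated post-enrichment shotgun library of single-end
#' reads: fixed read length, mean on-target fold coverage, the fraction of
#' the library deriving from non-target regions, a per-quality-score true
#' substitution error rate, a discrete base-quality distribution, and a
#' PCR-duplicate fraction. Defaults reflect an early-generation short-read
#' capture experiment: 36 bp single-end reads with roughly three quarters
#' of the library off target.
#'
#' @param read_length Read length in bp (>= 20; default 36).
#' @param mean_on_target_depth Mean fold coverage over target bases.
#' @param off_target_fraction Fraction of (non-duplicate) reads drawn from
#'   regions with no overlap with any target; default 0.75.
#' @param per_quality_error Named numeric vector mapping Phred scores to
#'   true substitution error rates, each in (0, 0.5). Defaults to the
#'   nominal Phred rate for every score in `quality_dist` (a
#'   well-calibrated sequencer).
#' @param quality_dist Named numeric vector of probabilities over Phred
#'   scores used to draw per-base quality values; default mass is
#'   concentrated at Q30-Q35.
#' @param duplicate_fraction Fraction of the final library that is PCR
#'   copies of another read (identical chromosome, position and strand;
#'   base calls and qualities re-drawn independently). Default 0.
#' @param nonunique_fraction Fraction of reads flagged MAPQ 0 to exercise
#'   the uniqueness filter; all other reads carry MAPQ 60. Default 0.02.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length = 36L,
                          mean_on_target_depth = 20,
                          off_target_fraction = 0.75,
                          per_quality_error = NULL,
                          quality_dist = c("10" = 0.02, "20" = 0.05,
                                           "25" = 0.08, "30" = 0.30,
                                           "33" = 0.20, "35" = 0.30,
                                           "40" = 0.05),
                          duplicate_fraction = 0,
                          nonunique_fraction = 0.02,
                          seed = 1L) {
  stopifnot(read_length >= 20, mean_on_target_depth >= 0,
            off_target_fraction >= 0, off_target_fraction < 1,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            nonunique_fraction >= 0, nonunique_fraction <= 1,
            abs(sum(quality_dist) - 1) < 1e-6)
  if (is.null(per_quality_error)) {
    q <- as.integer(names(quality_dist))
    per_quality_error <- setNames(pmin(pmax(10^(-q / 10), 1e-9), 0.4999),
                                  names(quality_dist))
  }
  if (any(per_quality_error <= 0 | per_quality_error >= 0.5))
    stop("per_quality_error rates must lie in (0, 0.5)")
  if (!all(names(quality_dist) %in% names(per_quality_error)))
    stop("per_quality_error must cover every quality in quality_dist")
  structure(list(read_length = as.integer(read_length),
                 mean_on_target_depth = mean_on_target_depth,
                 off_target_fraction = off_target_fraction,
                 per_quality_error = per_quality_error,
                 quality_dist = quality_dist,
                 duplicate_fraction = duplicate_fraction,
                 nonunique_fraction = nonunique_fraction,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate capture reads from a diploid individual
#'
#' Draws single-end reads over the capture targets (and, per
#' `off_target_fraction`, from regions with no target overlap), from the
#' two haplotypes with equal probability, injects base-call errors at the
#' per-quality rates, and appends PCR duplicates that share chromosome,
#' position, strand and source haplotype with their source read but carry
#' independently re-drawn base calls and qualities. Because the simulator
#' knows the true origin of every read, the output is an already-"mapped"
#' read table (the alignment step is bypassed): reads carry MAPQ 60 except
#' for a configurable fraction flagged MAPQ 0.
#'
#' On-target read counts per target are deterministic given the depth:
#' `round(depth * (width + read_length - 1) / read_length)` starts drawn
#' uniformly from the window of starts overlapping the target, which gives
#' uniform expected coverage `depth` at every target base.
#'
#' @param individual An `excapr_individual`.
#' @param targets GRanges of capture targets (e.g. from [design_targets()]).
#' @param spec A [read_sim_spec()].
#' @return A `data.table` of class `excapr_reads`, sorted by chromosome and
#'   position, with columns read_id, chrom, pos (1-based leftmost), strand,
#'   mapq, cigar, seq, qual (Phred+33), and simulation truth columns hap
#'   (source haplotype) and is_dup.
#' @export
simulate_reads <- function(individual, targets, spec) {
  stopifnot(inherits(individual, "excapr_individual"),
            inherits(spec, "read_sim_spec"))
  if (length(targets) == 0) stop("targets must be non-empty")
  set.seed(derive_seed(spec$seed, "simulate_reads"))
  L <- spec$read_length
  href <- individual$haplotypes$h1
  chrom_names <- names(href)
  chrom_len <- setNames(Biostrings::width(href), chrom_names)

  if (spec$mean_on_target_depth == 0) {
    warning("mean_on_target_depth is 0: returning an empty read set")
    empty <- data.table::data.table(
      read_id = character(0), chrom = character(0), pos = integer(0),
      strand = character(0), mapq = integer(0), cigar = character(0),
      seq = character(0), qual = character(0), hap = integer(0),
      is_dup = logical(0))
    data.table::setattr(empty, "class",
                        c("excapr_reads", class(empty)))
    return(empty)
  }

  tmerged <- GenomicRanges::reduce(targets, ignore.strand = TRUE)
  t_chrom <- as.character(GenomicRanges::seqnames(tmerged))
  t_start <- GenomicRanges::start(tmerged)
  t_end <- GenomicRanges::end(tmerged)
  t_w <- t_end - t_start + 1L

  # on-target reads: any start in [start - L + 1, end] overlaps the target
  n_t <- pmax(0L, as.integer(round(
    spec$mean_on_target_depth * (t_w + L - 1) / L)))
  on_chrom <- rep(t_chrom, n_t)
  lo <- pmax(1L, rep(t_start - L + 1L, n_t))
  hi <- pmin(unname(chrom_len[on_chrom]) - L + 1L, rep(t_end, n_t))
  on_pos <- lo + floor(runif(length(lo)) * (hi - lo + 1))
  on_pos <- as.integer(pmin(on_pos, hi))

  n_on <- length(on_pos)
  n_off <- as.integer(round(n_on * spec$off_target_fraction /
                              (1 - spec$off_target_fraction)))
  off_chrom <- character(0); off_pos <- integer(0)
  if (n_off > 0) {
    gaps <- list()
    for (cn in chrom_names) {
      sel <- t_chrom == cn
      g <- interval_gaps(t_start[sel], t_end[sel], chrom_len[[cn]])
      # a read placed at s in [gap_start, gap_end - L + 1] touches no target
      g <- g[g$end - g$start + 1L >= L, , drop = FALSE]
      if (nrow(g)) gaps[[cn]] <- data.frame(chrom = cn, g)
    }
    gaps <- do.call(rbind, gaps)
    if (is.null(gaps) || nrow(gaps) == 0) {
      warning("no off-target region can host a read; off-target reads skipped")
      n_off <- 0L
    } else {
      w <- gaps$end - gaps$start + 1L - L + 1L
      gi <- sample.int(nrow(gaps), n_off, replace = TRUE, prob = w)
      off_chrom <- gaps$chrom[gi]
      off_pos <- as.integer(gaps$start[gi] + floor(runif(n_off) * w[gi]))
    }
  }

  chrom <- c(on_chrom, off_chrom)
  pos <- c(on_pos, off_pos)
  n_base <- length(pos)
  strand <- sample(c("+", "-"), n_base, replace = TRUE)
  hap <- sample(c(1L, 2L), n_base, replace = TRUE)
  is_dup <- rep(FALSE, n_base)

  d <- spec$duplicate_fraction
  if (d > 0) {
    n_dup <- as.integer(round(n_base * d / (1 - d)))
    src <- sample.int(n_base, n_dup, replace = TRUE)
    chrom <- c(chrom, chrom[src])
    pos <- c(pos, pos[src])
    strand <- c(strand, strand[src])
    hap <- c(hap, hap[src])
    is_dup <- c(is_dup, rep(TRUE, n_dup))
  }
  n <- length(pos)

  # true bases from the source haplotype, as reference-oriented strings
  seqs <- character(n)
  for (h in 1:2) {
    hs <- individual$haplotypes[[h]]
    for (cn in chrom_names) {
      idx <- which(hap == h & chrom == cn)
      if (!length(idx)) next
      seqs[idx] <- substring(as.character(hs[[cn]]), pos[idx],
                             pos[idx] + L - 1L)
    }
  }

  # per-base qualities and sequencing errors over the concatenated library
  qlevels <- as.integer(names(spec$quality_dist))
  qvec <- qlevels[sample.int(length(qlevels), n * L, replace = TRUE,
                             prob = spec$quality_dist)]
  erate <- spec$per_quality_error[as.character(qvec)]
  err <- runif(n * L) < erate
  if (any(err)) {
    raw <- charToRaw(paste(seqs, collapse = ""))
    base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
    code <- integer(256)
    code[as.integer(base_raw)] <- 1:4
    idx <- which(err)
    cur <- code[as.integer(raw[idx])]
    keep <- cur > 0L                         # never mutate an N
    idx <- idx[keep]; cur <- cur[keep]
    shift <- sample.int(3L, length(idx), replace = TRUE)
    raw[idx] <- base_raw[((cur - 1L + shift) %% 4L) + 1L]
    big <- rawToChar(raw)
    seqs <- substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
  }
  bigq <- rawToChar(as.raw(qvec + 33L))
  quals <- substring(bigq, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)

  mapq <- rep(60L, n)
  if (spec$nonunique_fraction > 0)
    mapq[runif(n) < spec$nonunique_fraction] <- 0L

  reads <- data.table::data.table(
    read_id = sprintf("r%07d", seq_len(n)),
    chrom = chrom, pos = pos, strand = strand, mapq = mapq,
    cigar = paste0(L, "M"), seq = seqs, qual = quals,
    hap = hap, is_dup = is_dup)
  data.table::setorderv(reads, c("chrom", "pos", "read_id"))
  data.table::setattr(reads, "class", c("excapr_reads", class(reads)))
  reads[]
}
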