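check_sorted_reads <- function(reads) {
  if (nrow(reads) < 2) return(invisible(TRUE))
  r <- rle(reads$chrom)
  if (anyDuplicated(r$values))
    stop("reads must be grouped by chromosome (sort-order error)")
  pos_ok <- all(unlist(lapply(split(reads$pos, factor(reads$chrom,
                                                      levels = r$values)),
                              function(p) !is.unsorted(p))))
  if (!pos_ok)
    stop("reads must be sorted by position within chromosome ",
         "(sort-order error)")
  invisible(TRUE)
}

#' Filter mapped reads: uniqueness and on-target overlap
#'
#' Applies the two read-level acceptance criteria of the capture pipeline:
#' reads not uniquely mapped (mapping quality below `min_mapq`) are
#' discarded, and reads with no aligned base overlapping a capture target
#' are discarded. Input must be coordinate sorted.
#'
#' @param reads An `excapr_reads` table (coordinate sorted).
#' @param targets GRanges of capture targets.
#' @param min_mapq Minimum mapping quality counted as "uniquely mapped"
#'   (default 1, i.e. MAPQ > 0).
#' @return List with `reads` (the retained reads) and `stats`, a one-row
#'   data.frame: n_input, n_nonunique, n_offtarget, n_retained, and
#'   on_target_fraction (retained / uniquely mapped).
#' @export
filter_reads <- function(reads, targets, min_mapq = 1L) {
  check_sorted_reads(reads)
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(reads = reads,
                stats = data.frame(n_input = 0L, n_nonunique = 0L,
                                   n_offtarget = 0L, n_retained = 0L,
                                   on_target_fraction = NA_real_)))
  }
  rlen <- nchar(reads$seq)
  unique_ok <- reads$mapq >= min_mapq
  spans <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$pos, width = rlen))
  on_target <- GenomicRanges::countOverlaps(
    spans, targets, ignore.strand = TRUE) > 0
  keep <- unique_ok & on_target
  n_nonunique <- sum(!unique_ok)
  n_offtarget <- sum(unique_ok & !on_target)
  out <- reads[keep]
  stats <- data.frame(
    n_input = n_input, n_nonunique = n_nonunique,
    n_offtarget = n_offtarget, n_retained = sum(keep),
    on_target_fraction = if (sum(unique_ok) > 0)
      sum(keep) / sum(unique_ok) else NA_real_)
  list(reads = out, stats = stats)
}

#' Remove likely PCR duplicates
#'
#' Within every group of reads mapped identically by (chromosome, leftmost
#' position, strand), all but the read with the highest sum of per-base
#' Phred qualities are discarded; ties are broken toward the
#' lexicographically smallest read id, so the result is independent of
#' input order.
#'
#' @param reads An `excapr_reads` table (coordinate sorted).
#' @return List with `reads` (one survivor per duplicate group) and
#'   `stats`: n_input, n_duplicates_removed, duplicate_fraction.
#' @export
remove_pcr_duplicates <- function(reads) {
  check_sorted_reads(reads)
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(reads = reads,
                stats = data.frame(n_input = 0L, n_duplicates_removed = 0L,
                                   duplicate_fraction = NA_real_)))
  }
  dt <- data.table::as.data.table(reads)
  dt[, `.qsum` := qual_sum(qual)]
  data.table::setorderv(dt, c("chrom", "pos", "strand", ".qsum", "read_id"),
                        order = c(1L, 1L, 1L, -1L, 1L))
  keep <- dt[, .I[1L], by = c("chrom", "pos", "strand")]$V1
  out <- dt[sort(keep)]
  out[, `.qsum` := NULL]
  data.table::setorderv(out, c("chrom", "pos", "read_id"))
  data.table::setattr(out, "class", class(reads))
  n_removed <- n_input - nrow(out)
  list(reads = out[],
       stats = data.frame(n_input = n_input,
                          n_duplicates_removed = n_removed,
                          duplicate_fraction = n_removed / n_input))
}
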