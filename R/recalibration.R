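# Per-base expansion of an ungapped read table. Reads whose CIGAR is not a
# single full-length match (indels, clips) are skipped with a warning.
expand_read_bases <- function(reads) {
  n <- nrow(reads)
  L <- nchar(reads$seq)
  simple <- reads$cigar == paste0(L, "M")
  if (!all(simple)) {
    warning(sum(!simple), " read(s) with non-simple CIGAR skipped")
    reads <- reads[simple]
    n <- nrow(reads); L <- L[simple]
  }
  if (n == 0) {
    return(data.table::data.table(row = integer(0), chrom = character(0),
                                  pos = integer(0), code = integer(0),
                                  qual = integer(0), strand = character(0)))
  }
  rows <- rep.int(seq_len(n), L)
  code_lut <- integer(256)
  code_lut[as.integer(charToRaw("ACGT"))] <- 1:4
  data.table::data.table(
    row = rows,
    chrom = reads$chrom[rows],
    pos = reads$pos[rows] + (sequence(L) - 1L),
    code = code_lut[as.integer(charToRaw(paste(reads$seq, collapse = "")))],
    qual = as.integer(charToRaw(paste(reads$qual, collapse = ""))) - 33L,
    strand = reads$strand[rows])
}

reference_codes <- function(reference) {
  lapply(setNames(as.character(reference), names(reference)),
         encode_base_codes)
}

#' Build an empirical base-quality recalibration table
#'
#' Every aligned base of the (filtered, on-target, duplicate-free) reads
#' contributes to the bin of its sequencer-reported quality score; a
#' mismatch is any base differing from the reference at its aligned
#' position (reference N sites are skipped). All mismatches are treated as
#' sequencer error — the working assumption is that the great majority of
#' mismatches in on-target mappings are read errors, which is why tables
#' built from a highly diverged sample overstate the error rate and should
#' be averaged with a conspecific sample's table (see [average_tables()]).
#' The per-bin error rate is the ratio of mismatches to matches, and the
#' replacement quality is `round(-10*log10(e))` clamped to `[2, 41]` (a
#' bin with no mismatches gets quality 41).
#'
#' @param reads Filtered, duplicate-free `excapr_reads`.
#' @param reference Named [Biostrings::DNAStringSet] of the reference.
#' @param rate_denominator `"matches"` (the default; error = m/M) or
#'   `"aligned"` (error = m/(m+M)); the two differ by O(e^2).
#' @return A data.frame of class `recal_table`: q, matches, mismatches,
#'   error_rate, new_q, one row per observed quality score.
#' @export
build_recalibration_table <- function(reads, reference,
                                      rate_denominator = c("matches",
                                                           "aligned")) {
  rate_denominator <- match.arg(rate_denominator)
  bases <- expand_read_bases(reads)
  if (nrow(bases) == 0) stop("no aligned bases to recalibrate from")
  refc <- reference_codes(reference)
  bases[, ref_code := refc[[chrom[1]]][pos], by = "chrom"]
  bases <- bases[ref_code > 0L]
  if (nrow(bases) == 0) stop("no aligned bases to recalibrate from")
  tab <- bases[, .(matches = sum(code == ref_code),
                   mismatches = sum(code != ref_code)), by = "qual"]
  data.table::setorderv(tab, "qual")
  denom <- if (rate_denominator == "matches") tab$matches
           else tab$matches + tab$mismatches
  e <- ifelse(denom > 0, tab$mismatches / denom, Inf)
  out <- data.frame(q = tab$qual, matches = tab$matches,
                    mismatches = tab$mismatches, error_rate = e,
                    new_q = as.integer(error_to_phred(e)))
  class(out) <- c("recal_table", "data.frame")
  out
}

#' Average recalibration tables across samples
#'
#' The averaged error rate in each quality bin is the arithmetic mean of
#' the per-sample error rates over the samples in which the bin was
#' observed (had at least one matching base); bins observed in no sample
#' are absent. Replacement qualities are recomputed from the averaged
#' rates. This is the cross-sample correction used when one sample is so
#' diverged from the reference that its own mismatch rate would badly
#' overstate sequencer error.
#'
#' @param tables List of `recal_table` objects (at least one).
#' @return A `recal_table` with averaged error rates (matches/mismatches
#'   columns hold per-bin totals across samples, for reference).
#' @export
average_tables <- function(tables) {
  if (length(tables) == 0) stop("need at least one recalibration table")
  stopifnot(all(vapply(tables, inherits, TRUE, "recal_table")))
  dt <- data.table::rbindlist(lapply(tables, data.table::as.data.table))
  obs <- dt[matches > 0,
            .(error_rate = mean(error_rate),
              matches = sum(matches), mismatches = sum(mismatches)),
            by = "q"]
  data.table::setorderv(obs, "q")
  out <- data.frame(q = obs$q, matches = obs$matches,
                    mismatches = obs$mismatches,
                    error_rate = obs$error_rate,
                    new_q = as.integer(error_to_phred(obs$error_rate)))
  class(out) <- c("recal_table", "data.frame")
  out
}

#' Apply a recalibration table to read qualities
#'
#' Every base's quality score is replaced by the table's replacement
#' quality for its original score; scores absent from the table map to the
#' replacement quality of the nearest observed bin (ties toward the lower
#' score). Bases and read order are unchanged.
#'
#' @param reads An `excapr_reads` table.
#' @param table A `recal_table`.
#' @return The reads with recalibrated quality strings.
#' @export
apply_recalibration <- function(reads, table) {
  stopifnot(inherits(table, "recal_table"))
  if (nrow(reads) == 0) return(reads)
  present <- sort(unique(unlist(qual_string_to_int(unique(reads$qual)))))
  new_q <- vapply(present, function(q) {
    hit <- which(table$q == q)
    if (length(hit)) return(as.integer(table$new_q[hit[1]]))
    nearest <- order(abs(table$q - q), table$q)[1]
    as.integer(table$new_q[nearest])
  }, 0L)
  out <- data.table::copy(data.table::as.data.table(reads))
  out[, qual := chartr(intToUtf8(present + 33L),
                       intToUtf8(new_q + 33L), qual)]
  data.table::setattr(out, "class", class(reads))
  out[]
}

#' Write / read a recalibration table as TSV
#'
#' @param table A `recal_table`.
#' @param path TSV path (columns q, matches, mismatches, error_rate, new_q).
#' @export
write_recal_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recal_table
#' @export
read_recal_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("recal_table", "data.frame")
  out
}
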