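#' Write reads as SAM
#'
#' Emits a coordinate-sorted single-end SAM file (header with `@SQ` lines
#' taken from `chrom_lengths`). Sequences are stored reference-oriented, as
#' SAM requires; minus-strand reads get FLAG 16.
#'
#' @param reads An `excapr_reads` table (or any data.frame with read_id,
#'   chrom, pos, strand, mapq, cigar, seq, qual).
#' @param path Output SAM path.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @export
write_sam <- function(reads, path, chrom_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 reads$read_id, flag, reads$chrom, reads$pos, reads$mapq,
                 reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a single-end SAM file into a read table
#'
#' Converts via BAM ([Rsamtools::asBam]) and imports the fields this
#' pipeline uses. Unmapped records are dropped.
#'
#' @param path SAM file with a valid header.
#' @return An `excapr_reads` data.table (columns read_id, chrom, pos,
#'   strand, mapq, cigar, seq, qual), coordinate sorted.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  reads <- data.table::data.table(
    read_id = x$qname[keep],
    chrom = as.character(x$rname[keep]),
    pos = x$pos[keep],
    strand = ifelse(bitwAnd(x$flag[keep], 16L) > 0L, "-", "+"),
    mapq = as.integer(x$mapq[keep]),
    cigar = x$cigar[keep],
    seq = as.character(x$seq[keep]),
    qual = as.character(x$qual[keep]))
  data.table::setorderv(reads, c("chrom", "pos", "read_id"))
  data.table::setattr(reads, "class", c("excapr_reads", class(reads)))
  reads[]
}

#' Write reads as FASTQ (Phred+33)
#'
#' Minus-strand reads are reverse-complemented back to sequencing
#' orientation (qualities reversed accordingly).
#'
#' @param reads An `excapr_reads` table.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  q <- reads$qual
  neg <- reads$strand == "-"
  if (any(neg)) {
    s[neg] <- Biostrings::reverseComplement(s[neg])
    q[neg] <- vapply(q[neg], function(x)
      intToUtf8(rev(utf8ToInt(x))), "")
  }
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(q))
  invisible(path)
}
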