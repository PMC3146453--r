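#' Write consensus calls as single-sample VCF 4.2
#'
#' SNV-only records with GT, DP and GQ. Heterozygotes carrying the
#' reference allele are written `0/1`; homozygous non-reference calls
#' `1/1`; heterozygotes with two non-reference alleles get both as ALT
#' and genotype `1/2`. Homozygous-reference calls are written `0/0` with
#' ALT `.` (pass variants through [classify_variants()] first to emit
#' variants only).
#'
#' @param calls An `excapr_calls` or `excapr_variants` data.frame.
#' @param path Output VCF path.
#' @param sample_name Sample column name.
#' @param chrom_lengths Optional named vector for `##contig` lines.
#' @export
write_calls_vcf <- function(calls, path, sample_name = "sample1",
                            chrom_lengths = NULL) {
  al <- iupac_to_alleles(calls$genotype)
  ref <- toupper(calls$ref)
  gt <- character(nrow(calls))
  alt <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- unique(c(al[i, 1], al[i, 2]))
    alts <- setdiff(a, ref[i])
    if (length(alts) == 0) { alt[i] <- "."; gt[i] <- "0/0" }
    else if (length(a) == 1) { alt[i] <- alts; gt[i] <- "1/1" }
    else if (length(alts) == 1) { alt[i] <- alts; gt[i] <- "0/1" }
    else { alt[i] <- paste(alts, collapse = ","); gt[i] <- "1/2" }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=excapr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0('##FORMAT=<ID=GQ,Number=1,Type=Integer,',
           'Description="Consensus genotype quality">'))
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                       "\tFORMAT\t", sample_name))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%d\t.\t.\tGT:DP:GQ\t%s:%d:%d",
                 calls$chrom, calls$pos, ref, alt, as.integer(calls$qual),
                 gt, as.integer(calls$depth), as.integer(calls$qual))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write calls or variants as TSV
#'
#' Mirror of the VCF output: chrom, pos (1-based), ref, genotype (IUPAC),
#' qual, depth (plus class for classified variants).
#'
#' @param calls An `excapr_calls` or `excapr_variants` data.frame.
#' @param path Output TSV path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
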