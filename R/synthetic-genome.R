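#' Specification for a synthetic annotated reference genome
#'
#' Describes a multi-chromosome genome with gene models (ordered,
#' non-overlapping exons; one exon per gene flagged as containing the 5'
#' UTR), standing in for an annotated draft genome such as a livestock
#' reference assembly.
#'
#' @param chromosome_lengths Integer vector of chromosome lengths in bp.
#' @param n_genes Total number of genes; allocated to chromosomes
#'   proportionally to length by largest-remainder apportionment.
#' @param exons_per_gene Length-2 integer range, exons drawn uniformly.
#' @param exon_length Length-2 integer range of exon lengths in bp.
#' @param intron_length Length-2 integer range of intron lengths in bp.
#' @param gc_content Expected GC fraction of the simulated sequence.
#' @param n_candidate_genes Number of genes emitted as the named
#'   candidate-gene list (all of whose exons are captured regardless of the
#'   per-gene cap).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chromosome_lengths, n_genes,
                        exons_per_gene = c(4L, 8L),
                        exon_length = c(80L, 300L),
                        intron_length = c(100L, 300L),
                        gc_content = 0.42,
                        n_candidate_genes = 0L,
                        seed = 1L) {
  stopifnot(length(chromosome_lengths) >= 1, all(chromosome_lengths > 0),
            n_genes >= 1, length(exons_per_gene) == 2,
            exons_per_gene[1] >= 1, diff(exons_per_gene) >= 0,
            all(exon_length > 0), all(intron_length > 0),
            gc_content > 0, gc_content < 1,
            n_candidate_genes >= 0, n_candidate_genes <= n_genes)
  structure(list(
    chromosome_lengths = as.integer(chromosome_lengths),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    gc_content = gc_content,
    n_candidate_genes = as.integer(n_candidate_genes),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Generate a synthetic annotated reference genome
#'
#' Produces random chromosome sequences at the requested GC content and
#' lays out gene models with ordered, non-overlapping exons. Genes are
#' assigned to chromosomes proportionally to chromosome length
#' (largest-remainder apportionment) and placed in equal-width slots so
#' they never overlap. The first exon in transcription order (the
#' highest-coordinate exon for minus-strand genes) is flagged as containing
#' the 5' UTR. A subset of genes is emitted as the candidate-gene list.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `excapr_genome`: list with `seqs`
#'   (named [Biostrings::DNAStringSet]), `genes` (GRanges with `gene_id`,
#'   strand), `exons` (GRanges with `gene_id`, `exon_ordinal` in
#'   transcription order, `utr5` flag), and `candidate_ids`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(spec$seed, "reference"))
  chrom_names <- paste0("chr", seq_along(spec$chromosome_lengths))
  lens <- spec$chromosome_lengths
  names(lens) <- chrom_names

  genes_per_chrom <- apportion_largest_remainder(lens, spec$n_genes)

  seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE,
                 prob = c((1 - spec$gc_content) / 2, spec$gc_content / 2,
                          spec$gc_content / 2, (1 - spec$gc_content) / 2)),
          collapse = "")
  }, character(1)))
  names(seqs) <- chrom_names

  gene_rows <- list()
  exon_rows <- list()
  gi <- 0L
  for (ci in seq_along(chrom_names)) {
    nc <- genes_per_chrom[ci]
    if (nc == 0L) next
    slot <- lens[ci] %/% nc
    for (k in seq_len(nc)) {
      gi <- gi + 1L
      n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
      ex_len <- sample(spec$exon_length[1]:spec$exon_length[2], n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1)
        sample(spec$intron_length[1]:spec$intron_length[2], n_ex - 1L,
               replace = TRUE) else integer(0)
      gene_len <- sum(ex_len) + sum(in_len)
      if (gene_len > slot)
        stop("chromosome ", chrom_names[ci], " too short to host ", nc,
             " genes: gene of ", gene_len, " bp exceeds the ", slot,
             " bp slot; reduce gene count or sizes")
      offset <- sample.int(slot - gene_len + 1L, 1L)
      gstart <- (k - 1L) * slot + offset
      ex_start <- gstart + cumsum(c(0L, head(ex_len, -1) + in_len))
      ex_end <- ex_start + ex_len - 1L
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%04d", gi)
      ordinal <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      gene_rows[[gi]] <- data.frame(
        chrom = chrom_names[ci], start = gstart,
        end = gstart + gene_len - 1L, strand = strand, gene_id = gid)
      exon_rows[[gi]] <- data.frame(
        chrom = chrom_names[ci], start = ex_start, end = ex_end,
        strand = strand, gene_id = gid, exon_ordinal = ordinal,
        utr5 = ordinal == 1L)
    }
  }
  genes_df <- do.call(rbind, gene_rows)
  exons_df <- do.call(rbind, exon_rows)

  genes <- GenomicRanges::GRanges(
    genes_df$chrom, IRanges::IRanges(genes_df$start, genes_df$end),
    strand = genes_df$strand, gene_id = genes_df$gene_id,
    seqinfo = GenomeInfoDb::Seqinfo(chrom_names, unname(lens)))
  exons <- GenomicRanges::GRanges(
    exons_df$chrom, IRanges::IRanges(exons_df$start, exons_df$end),
    strand = exons_df$strand, gene_id = exons_df$gene_id,
    exon_ordinal = exons_df$exon_ordinal, utr5 = exons_df$utr5,
    seqinfo = GenomeInfoDb::Seqinfo(chrom_names, unname(lens)))

  candidate_ids <- if (spec$n_candidate_genes > 0)
    sort(sample(genes_df$gene_id, spec$n_candidate_genes)) else character(0)

  structure(list(seqs = seqs, genes = genes, exons = exons,
                 candidate_ids = candidate_ids, spec = spec),
            class = "excapr_genome")
}

#' Write a synthetic genome to disk
#'
#' Writes the reference FASTA, a GFF3 annotation (gene and exon features,
#' with `exon_ordinal` and `utr5` attributes) and the candidate-gene list
#' (one gene id per line).
#'
#' @param genome An `excapr_genome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named list).
#' @export
write_reference <- function(genome, dir) {
  stopifnot(inherits(genome, "excapr_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "annotation.gff3")
  cand <- file.path(dir, "candidate_genes.txt")
  Biostrings::writeXStringSet(genome$seqs, fa)
  g <- genome$genes
  S4Vectors::mcols(g)$type <- "gene"
  S4Vectors::mcols(g)$ID <- S4Vectors::mcols(g)$gene_id
  e <- genome$exons
  S4Vectors::mcols(e)$type <- "exon"
  S4Vectors::mcols(e)$ID <- paste0(S4Vectors::mcols(e)$gene_id, ".e",
                                   S4Vectors::mcols(e)$exon_ordinal)
  S4Vectors::mcols(e)$Parent <- S4Vectors::mcols(e)$gene_id
  rtracklayer::export(c(GenomicRanges::granges(g, use.mcols = TRUE),
                        GenomicRanges::granges(e, use.mcols = TRUE)),
                      gff, format = "gff3")
  writeLines(genome$candidate_ids, cand)
  invisible(list(fasta = fa, gff3 = gff, candidates = cand))
}

#' Read an exon annotation from GFF3
#'
#' Expects gene and exon features; exon features carry `gene_id` (or
#' `Parent`), and optionally `exon_ordinal` and `utr5` attributes. When
#' `exon_ordinal`/`utr5` are absent they are inferred from transcription
#' order (first exon 5'-most on the annotated strand).
#'
#' @param path GFF3 file.
#' @return List with `genes` and `exons` GRanges in the layout produced by
#'   [generate_reference()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  genes <- gr[mc$type == "gene"]
  exons <- gr[mc$type == "exon"]
  gid <- S4Vectors::mcols(exons)$gene_id
  if (is.null(gid)) {
    gid <- as.character(S4Vectors::mcols(exons)$Parent)
  }
  S4Vectors::mcols(exons)$gene_id <- gid
  if (is.null(S4Vectors::mcols(genes)$gene_id))
    S4Vectors::mcols(genes)$gene_id <- S4Vectors::mcols(genes)$ID
  ord <- S4Vectors::mcols(exons)$exon_ordinal
  if (is.null(ord)) {
    ord <- unlist(lapply(split(seq_along(exons), gid), function(idx) {
      st <- as.character(GenomicRanges::strand(exons[idx[1]]))
      r <- rank(GenomicRanges::start(exons[idx]), ties.method = "first")
      if (st == "-") length(idx) + 1L - r else r
    }))[order(unlist(split(seq_along(exons), gid)))]
  }
  S4Vectors::mcols(exons)$exon_ordinal <- as.integer(ord)
  u5 <- S4Vectors::mcols(exons)$utr5
  if (is.null(u5)) u5 <- as.integer(ord) == 1L
  S4Vectors::mcols(exons)$utr5 <- as.logical(u5)
  list(genes = genes, exons = exons)
}
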