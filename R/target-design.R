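#' Configuration for exon capture target design
#'
#' Defaults follow the published design rules for a ~3 Mb exome-subset
#' capture: at most 1,500 exon bp per gene outside the named candidate
#' genes, no exons under 40 bp, 750 bp sampled from each end of the 5'
#' terminal exon when every exon of a gene exceeds the cap, and a
#' redundancy screen rejecting any exon sharing a 40 bp window at more
#' than 90% identity with an exon already collected.
#'
#' @param per_gene_bp_cap Per-gene exon bp cap for non-candidate genes.
#' @param min_exon_bp Minimum exon length for non-candidate genes.
#' @param long_first_exon_end_bp Length sampled from each end of the 5'
#'   terminal exon when every exon exceeds the cap.
#' @param redundancy_window_bp Window length of the redundancy screen.
#' @param redundancy_identity Identity fraction that must be strictly
#'   exceeded for rejection.
#' @param n_genomewide_genes Number of genes to sample genome-wide
#'   (in addition to the candidate genes).
#' @param total_bp_budget Total target bp ceiling; genome-wide sampling
#'   stops once it is reached (the gene in progress is completed).
#' @param candidate_gene_ids Character vector of genes whose complete exon
#'   sets are collected, exempt from the cap and the minimum length.
#' @return An object of class `design_config`.
#' @export
design_config <- function(per_gene_bp_cap = 1500L, min_exon_bp = 40L,
                          long_first_exon_end_bp = 750L,
                          redundancy_window_bp = 40L,
                          redundancy_identity = 0.90,
                          n_genomewide_genes = 2367L,
                          total_bp_budget = 3e6,
                          candidate_gene_ids = character(0)) {
  stopifnot(per_gene_bp_cap >= min_exon_bp, min_exon_bp > 0,
            long_first_exon_end_bp > 0, redundancy_window_bp > 0,
            redundancy_identity > 0, redundancy_identity < 1,
            n_genomewide_genes >= 0, total_bp_budget > 0)
  structure(list(per_gene_bp_cap = as.integer(per_gene_bp_cap),
                 min_exon_bp = as.integer(min_exon_bp),
                 long_first_exon_end_bp = as.integer(long_first_exon_end_bp),
                 redundancy_window_bp = as.integer(redundancy_window_bp),
                 redundancy_identity = redundancy_identity,
                 n_genomewide_genes = as.integer(n_genomewide_genes),
                 total_bp_budget = total_bp_budget,
                 candidate_gene_ids = as.character(candidate_gene_ids)),
            class = "design_config")
}

gene_midpoint <- function(start, end) (start + end) %/% 2L

#' Genome-wide gene sampling for capture design
#'
#' Visits chromosomes round-robin, longer chromosomes proportionally more
#' often (largest-remainder apportionment of the `n_genes` visits by
#' chromosome bp). On each visit the selected gene is the not-yet-selected
#' gene whose midpoint is closest to the midpoint of the currently largest
#' contiguous span of that chromosome containing no selected gene's
#' footprint (footprints of `already_selected` genes count as sampled).
#' Ties — equal-length spans, or two genes equidistant from a span
#' midpoint — are broken toward the lower genomic coordinate. A chromosome
#' whose genes are exhausted is skipped with a warning and its remaining
#' visits are redistributed round-robin over the chromosomes that still
#' have genes.
#'
#' @param genes GRanges of gene bodies with a `gene_id` column.
#' @param chromosome_lengths Named integer vector covering every annotated
#'   chromosome.
#' @param n_genes Number of genes to select.
#' @param already_selected Character vector of gene ids to exclude (their
#'   footprints still mask the spans).
#' @return Character vector of `n_genes` gene ids in selection order.
#' @export
select_genes_genomewide <- function(genes, chromosome_lengths, n_genes,
                                    already_selected = character(0)) {
  gid <- S4Vectors::mcols(genes)$gene_id
  chrom <- as.character(GenomicRanges::seqnames(genes))
  if (!all(chrom %in% names(chromosome_lengths)))
    stop("chromosome_lengths must cover all annotated chromosomes")
  avail_total <- sum(!gid %in% already_selected)
  if (n_genes > avail_total)
    stop("n_genes exceeds the number of available genes")
  if (n_genes == 0) return(character(0))

  gstart <- GenomicRanges::start(genes)
  gend <- GenomicRanges::end(genes)
  gmid <- gene_midpoint(gstart, gend)

  chroms <- names(chromosome_lengths)
  visits <- apportion_largest_remainder(as.numeric(chromosome_lengths),
                                        n_genes)
  names(visits) <- chroms
  state <- lapply(chroms, function(cn) {
    on <- chrom == cn
    sel <- on & gid %in% already_selected
    list(avail = which(on & !gid %in% already_selected),
         fp_start = gstart[sel], fp_end = gend[sel])
  })
  names(state) <- chroms

  pick_one <- function(cn) {
    st <- state[[cn]]
    gaps <- interval_gaps(st$fp_start, st$fp_end, chromosome_lengths[[cn]])
    if (nrow(gaps) == 0) gaps <- data.frame(start = 1L,
                                            end = chromosome_lengths[[cn]])
    w <- gaps$end - gaps$start + 1L
    g <- gaps[order(-w, gaps$start)[1], ]
    span_mid <- gene_midpoint(g$start, g$end)
    cand <- st$avail
    dist <- abs(gmid[cand] - span_mid)
    j <- cand[order(dist, gmid[cand], gstart[cand])[1]]
    state[[cn]]$avail <<- setdiff(st$avail, j)
    state[[cn]]$fp_start <<- c(st$fp_start, gstart[j])
    state[[cn]]$fp_end <<- c(st$fp_end, gend[j])
    j
  }

  selected <- integer(0)
  exhausted_warned <- character(0)
  while (length(selected) < n_genes) {
    progressed <- FALSE
    for (cn in chroms) {
      if (length(selected) >= n_genes) break
      if (visits[cn] <= 0) next
      if (length(state[[cn]]$avail) == 0) {
        if (!cn %in% exhausted_warned) {
          warning("chromosome ", cn,
                  " has no genes left; redistributing its visits")
          exhausted_warned <- c(exhausted_warned, cn)
        }
        visits[cn] <- 0L
        next
      }
      selected <- c(selected, pick_one(cn))
      visits[cn] <- visits[cn] - 1L
      progressed <- TRUE
    }
    if (!progressed) {
      # quotas used up (or forfeited): keep cycling chromosomes with genes
      open <- chroms[vapply(state, function(s) length(s$avail) > 0, TRUE)]
      if (length(open) == 0) break
      visits[open] <- visits[open] + 1L
    }
  }
  gid[selected]
}

#' Select capture exons for one gene
#'
#' Candidate genes contribute all their exons, exempt from the bp cap and
#' the minimum exon length. For other genes: the exon containing the 5'
#' UTR is always collected (when it meets the minimum length), then exons
#' are drawn uniformly at random without replacement from the remaining
#' exons of at least `min_exon_bp` until adding one brings the cumulative
#' bp above `per_gene_bp_cap` — that crossing exon is included, then
#' selection stops. If every exon of the gene is longer than the cap, the
#' gene instead contributes `long_first_exon_end_bp` from each end of its
#' 5' terminal exon. Draws use the session RNG; seed upstream for
#' reproducibility.
#'
#' @param gene_exons GRanges of the gene's exons with `gene_id`,
#'   `exon_ordinal` (transcription order) and `utr5` columns.
#' @param config A [design_config()].
#' @param candidate Logical: is this one of the named candidate genes?
#' @return GRanges of selected targets with `gene_id`, `exon_ordinal` and
#'   `role` (one of utr5/sampled/candidate_gene/long_first_exon_end).
#' @export
select_exons_for_gene <- function(gene_exons, config, candidate = FALSE) {
  stopifnot(length(gene_exons) >= 1)
  mc <- S4Vectors::mcols(gene_exons)
  if (is.null(mc$utr5) || !any(mc$utr5))
    stop("annotation error: gene ", mc$gene_id[1] %||% "?",
         " has no exon flagged as containing the 5' UTR")
  wid <- GenomicRanges::width(gene_exons)
  role <- function(gr, r) { S4Vectors::mcols(gr)$role <- r; gr }

  if (candidate) return(role(gene_exons, "candidate_gene"))

  if (all(wid > config$per_gene_bp_cap)) {
    first <- gene_exons[mc$exon_ordinal == 1L][1]
    len <- config$long_first_exon_end_bp
    left <- GenomicRanges::resize(first, len, fix = "start",
                                  ignore.strand = TRUE)
    right <- GenomicRanges::resize(first, len, fix = "end",
                                   ignore.strand = TRUE)
    out <- c(left, right)
    return(role(out, "long_first_exon_end"))
  }

  utr_idx <- which(mc$utr5)[1]
  chosen <- integer(0)
  total <- 0L
  if (wid[utr_idx] >= config$min_exon_bp) {
    chosen <- utr_idx
    total <- wid[utr_idx]
  }
  pool <- setdiff(which(wid >= config$min_exon_bp), utr_idx)
  while (total <= config$per_gene_bp_cap && length(pool) > 0) {
    pick <- if (length(pool) == 1) pool else sample(pool, 1L)
    pool <- setdiff(pool, pick)
    chosen <- c(chosen, pick)
    total <- total + wid[pick]
  }
  out <- gene_exons[chosen]
  S4Vectors::mcols(out)$role <-
    ifelse(S4Vectors::mcols(out)$utr5, "utr5", "sampled")
  out
}

#' Design an exon capture target set
#'
#' Runs the full design: the candidate genes' complete exon sets first,
#' then genome-wide gene sampling (see [select_genes_genomewide()]) until
#' `n_genomewide_genes` genes have been processed or the total bp budget
#' is reached, whichever comes first (the gene in progress is completed,
#' so the budget can be exceeded by at most one gene's contribution).
#' Every emitted target must pass the redundancy screen against all
#' targets emitted before it, in emission order.
#'
#' @param genome An `excapr_genome`, or a list with `seqs` (DNAStringSet),
#'   `genes` and `exons` GRanges in the same layout.
#' @param config A [design_config()].
#' @param seed Integer seed for the per-gene random exon draws.
#' @return An object of class `excapr_design`: list with `targets`
#'   (sorted GRanges; `gene_id`, `exon_ordinal`, `role`), `report`
#'   (per-gene data.frame: gene_id, n_exons_selected, total_bp, roles),
#'   `total_bp`, and `n_rejected_redundant`.
#' @export
design_targets <- function(genome, config, seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  set.seed(derive_seed(seed, "design"))
  exons <- genome$exons
  genes <- genome$genes
  gid_all <- S4Vectors::mcols(genes)$gene_id
  exon_gid <- S4Vectors::mcols(exons)$gene_id
  chrom_len <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))

  cand_ids <- intersect(config$candidate_gene_ids, gid_all)
  cand_bp <- sum(GenomicRanges::width(exons[exon_gid %in% cand_ids]))
  if (cand_bp > config$total_bp_budget)
    stop("total_bp_budget (", config$total_bp_budget,
         ") smaller than the candidate genes' exon footprint (", cand_bp, ")")

  collected <- character(0)
  out <- list()
  report <- list()
  total_bp <- 0L
  n_rejected <- 0L

  process_gene <- function(g, candidate) {
    ge <- exons[exon_gid == g]
    ge <- ge[order(S4Vectors::mcols(ge)$exon_ordinal)]
    sel <- select_exons_for_gene(ge, config, candidate = candidate)
    if (length(sel) == 0) return(invisible(NULL))
    seqs <- as.character(Biostrings::extractAt(
      genome$seqs[[as.character(GenomicRanges::seqnames(sel))[1]]],
      IRanges::IRanges(GenomicRanges::start(sel),
                       GenomicRanges::end(sel))))
    keep <- logical(length(sel))
    for (i in seq_along(sel)) {
      ok <- redundancy_filter(seqs[i], collected,
                              window = config$redundancy_window_bp,
                              identity = config$redundancy_identity)
      keep[i] <- ok
      if (ok) collected <<- c(collected, seqs[i])
      else n_rejected <<- n_rejected + 1L
    }
    sel <- sel[keep]
    if (length(sel)) {
      out[[length(out) + 1L]] <<- sel
      total_bp <<- total_bp + sum(GenomicRanges::width(sel))
    }
    report[[length(report) + 1L]] <<- data.frame(
      gene_id = g, n_exons_selected = length(sel),
      total_bp = sum(GenomicRanges::width(sel)),
      roles = paste(unique(S4Vectors::mcols(sel)$role), collapse = ","))
    invisible(NULL)
  }

  for (g in sort(cand_ids)) process_gene(g, candidate = TRUE)

  if (config$n_genomewide_genes > 0) {
    n_avail <- sum(!gid_all %in% cand_ids)
    n_gw <- min(config$n_genomewide_genes, n_avail)
    gw <- select_genes_genomewide(genes, chrom_len, n_gw,
                                  already_selected = cand_ids)
    for (g in gw) {
      if (total_bp >= config$total_bp_budget) break
      process_gene(g, candidate = FALSE)
    }
  }

  targets <- if (length(out)) sort(do.call(c, out), ignore.strand = TRUE)
             else GenomicRanges::GRanges()
  structure(list(targets = targets,
                 report = do.call(rbind, report) %||% data.frame(),
                 total_bp = total_bp, n_rejected_redundant = n_rejected),
            class = "excapr_design")
}

#' Export capture targets as BED6
#'
#' Names are `gene_id|exon_ordinal|role`; scores 0. Coordinates follow the
#' BED convention (0-based half-open), converted from the package's
#' 1-based closed internal representation by the exporter.
#'
#' @param design An `excapr_design` (or a targets GRanges).
#' @param path Output BED path.
#' @export
export_targets_bed <- function(design, path) {
  gr <- if (inherits(design, "excapr_design")) design$targets else design
  mc <- S4Vectors::mcols(gr)
  nm <- paste(mc$gene_id, mc$exon_ordinal, mc$role, sep = "|")
  bed <- GenomicRanges::granges(gr)
  S4Vectors::mcols(bed)$name <- nm
  S4Vectors::mcols(bed)$score <- 0L
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Read capture targets from BED
#'
#' @param path BED file whose name field is `gene_id|exon_ordinal|role`
#'   (plain names are kept as `gene_id` with role `NA`).
#' @return GRanges with `gene_id`, `exon_ordinal`, `role`.
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  parts <- strsplit(nm %||% rep(NA_character_, length(gr)), "|", fixed = TRUE)
  S4Vectors::mcols(gr)$gene_id <- vapply(parts, `[`, "", 1)
  S4Vectors::mcols(gr)$exon_ordinal <- suppressWarnings(
    as.integer(vapply(parts, function(p) p[2] %||% NA_character_, "")))
  S4Vectors::mcols(gr)$role <- vapply(parts, function(p)
    if (length(p) >= 3) p[3] else NA_character_, "")
  gr
}
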