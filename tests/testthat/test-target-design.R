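# independent span-tracking oracle for genome-wide gene sampling: keeps
# explicit per-chromosome footprint lists and picks by exhaustive search
oracle_select_genes <- function(genes_df, chrom_len, n, already = character(0)) {
  sel <- character(0)
  fp <- lapply(chrom_len, function(len) {
    data.frame(start = integer(0), end = integer(0))
  })
  for (g in intersect(already, genes_df$gene_id)) {
    r <- genes_df[genes_df$gene_id == g, ]
    fp[[r$chrom]] <- rbind(fp[[r$chrom]], data.frame(start = r$start,
                                                     end = r$end))
  }
  visits <- local({
    q <- n * chrom_len / sum(chrom_len)
    b <- floor(q); left <- n - sum(b)
    if (left > 0) {
      ord <- order(-(q - b), seq_along(q))
      b[ord[seq_len(left)]] <- b[ord[seq_len(left)]] + 1
    }
    b
  })
  chroms <- names(chrom_len)
  repeat {
    if (length(sel) >= n) break
    moved <- FALSE
    for (cn in chroms) {
      if (length(sel) >= n) break
      if (visits[cn] <= 0) next
      avail <- genes_df[genes_df$chrom == cn &
                          !genes_df$gene_id %in% c(sel, already), ]
      if (nrow(avail) == 0) { visits[cn] <- 0; next }
      # largest free span by exhaustive scan over positions
      occupied <- rep(FALSE, chrom_len[[cn]])
      f <- fp[[cn]]
      if (nrow(f)) for (i in seq_len(nrow(f)))
        occupied[f$start[i]:f$end[i]] <- TRUE
      r <- rle(occupied)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      free <- which(!r$values)
      w <- r$lengths[free]
      best <- free[order(-w, starts[free])[1]]
      smid <- (starts[best] + ends[best]) %/% 2
      mid <- (avail$start + avail$end) %/% 2
      pick <- avail[order(abs(mid - smid), mid, avail$start)[1], ]
      sel <- c(sel, pick$gene_id)
      fp[[cn]] <- rbind(fp[[cn]], data.frame(start = pick$start,
                                             end = pick$end))
      visits[cn] <- visits[cn] - 1
      moved <- TRUE
    }
    if (!moved) {
      open <- chroms[vapply(chroms, function(cn)
        any(genes_df$chrom == cn &
              !genes_df$gene_id %in% c(sel, already)), TRUE)]
      if (length(open) == 0) break
      visits[open] <- visits[open] + 1
    }
  }
  sel
}

genes_gr <- function(df, chrom_len) {
  GRanges(df$chrom, IRanges(df$start, df$end), strand = "+",
          gene_id = df$gene_id,
          seqinfo = GenomeInfoDb::Seqinfo(names(chrom_len),
                                          unname(chrom_len)))
}

test_that("one chromosome, one gene, n = 1 selects that gene", {
  len <- c(chr1 = 10000L)
  df <- data.frame(chrom = "chr1", start = 4000L, end = 5000L,
                   gene_id = "gA")
  expect_equal(select_genes_genomewide(genes_gr(df, len), len, 1), "gA")
})

test_that("visits are apportioned 20/10 for 100kb and 50kb chromosomes", {
  len <- c(chr1 = 100000L, chr2 = 50000L)
  set.seed(42)
  df <- rbind(
    data.frame(chrom = "chr1", start = sort(sample.int(98000L, 25)),
               gene_id = sprintf("a%02d", 1:25)),
    data.frame(chrom = "chr2", start = sort(sample.int(48000L, 25)),
               gene_id = sprintf("b%02d", 1:25)))
  df$end <- df$start + 500L
  sel <- select_genes_genomewide(genes_gr(df, len), len, 30)
  expect_length(sel, 30)
  expect_equal(sum(startsWith(sel, "a")), 20L)
  expect_equal(sum(startsWith(sel, "b")), 10L)
})

test_that("gene picks follow the largest-free-span midpoint rule", {
  len <- c(chr1 = 100000L)
  df <- data.frame(chrom = "chr1",
                   start = c(9000L, 49000L, 89000L),
                   end = c(11000L, 51000L, 91000L),
                   gene_id = c("g10k", "g50k", "g90k"))
  sel <- select_genes_genomewide(genes_gr(df, len), len, 3)
  expect_equal(sel[1], "g50k")   # nearest the whole-chromosome midpoint
  expect_equal(sel, oracle_select_genes(df, len, 3))
})

test_that("selection matches the span-tracking oracle on random layouts", {
  for (seed in 1:5) {
    set.seed(seed)
    len <- c(chr1 = 60000L, chr2 = 40000L)
    df <- rbind(
      data.frame(chrom = "chr1", start = sort(sample.int(58000L, 12)),
                 gene_id = sprintf("a%02d", 1:12)),
      data.frame(chrom = "chr2", start = sort(sample.int(38000L, 8)),
                 gene_id = sprintf("b%02d", 1:8)))
    df$end <- df$start + sample(200:800, 20, replace = TRUE)
    already <- df$gene_id[sample.int(20, 2)]
    sel <- select_genes_genomewide(genes_gr(df, len), len, 10, already)
    expect_identical(sel, oracle_select_genes(df, len, 10, already))
    expect_length(intersect(sel, already), 0)
  }
})

test_that("an exhausted chromosome forfeits its visits with a warning", {
  len <- c(chr1 = 100000L, chr2 = 50000L)
  df <- rbind(
    data.frame(chrom = "chr1", start = seq(1000L, 91000L, 10000L),
               gene_id = sprintf("a%02d", 1:10)),
    data.frame(chrom = "chr2", start = c(10000L, 30000L),
               gene_id = c("b01", "b02")))
  df$end <- df$start + 500L
  expect_warning(sel <- select_genes_genomewide(genes_gr(df, len), len, 12),
                 "redistribut")
  expect_length(sel, 12)
  expect_setequal(sel, df$gene_id)
})

test_that("n_genes above the available gene count errors", {
  len <- c(chr1 = 10000L)
  df <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                   gene_id = "gA")
  expect_error(select_genes_genomewide(genes_gr(df, len), len, 2),
               "exceeds")
})

make_gene <- function(widths, utr_idx = 1L, start = 1000L, gap = 500L,
                      strand = "+", gene_id = "g1") {
  starts <- start + cumsum(c(0L, head(widths, -1) + gap))
  n <- length(widths)
  ordinal <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  GRanges("chr1", IRanges(starts, width = widths), strand = strand,
          gene_id = gene_id, exon_ordinal = ordinal,
          utr5 = ordinal == utr_idx)
}

test_that("candidate genes contribute all exons regardless of limits", {
  g <- make_gene(c(30L, 2000L, 60L))
  sel <- select_exons_for_gene(g, design_config(), candidate = TRUE)
  expect_length(sel, 3)
  expect_equal(sort(width(sel)), c(30L, 60L, 2000L))
  expect_true(all(sel$role == "candidate_gene"))
})

test_that("selection always holds the UTR exon and obeys the cap rule", {
  g <- make_gene(c(400L, 300L, 400L, 500L, 600L))
  cfg <- design_config()
  for (seed in 1:40) {
    set.seed(seed)
    sel <- select_exons_for_gene(g, cfg)
    expect_true(any(sel$utr5))
    expect_equal(sel$role[1], "utr5")
    tot <- sum(width(sel))
    expect_gt(tot, 1500)
    # removing the last-drawn exon brings the total back under the cap
    expect_lte(tot - width(sel)[length(sel)], 1500)
  }
})

test_that("a gene with only >cap exons yields two 750 bp end targets", {
  for (st in c("+", "-")) {
    g <- make_gene(c(1600L, 1700L), strand = st)
    sel <- select_exons_for_gene(g, design_config())
    expect_length(sel, 2)
    expect_true(all(width(sel) == 750L))
    expect_true(all(sel$role == "long_first_exon_end"))
    first <- g[g$exon_ordinal == 1L]
    expect_equal(min(start(sel)), start(first))
    expect_equal(max(end(sel)), end(first))
  }
})

test_that("sub-minimum exons are never drawn for non-candidate genes", {
  g <- make_gene(c(400L, 39L, 200L))
  for (seed in 1:100) {
    set.seed(seed)
    sel <- select_exons_for_gene(g, design_config())
    expect_false(39L %in% width(sel))
  }
})

test_that("a gene with no UTR flag raises an annotation error", {
  g <- make_gene(c(400L, 300L))
  g$utr5 <- FALSE
  expect_error(select_exons_for_gene(g, design_config()), "UTR")
})

test_that("redundancy screen accepts against an empty collection", {
  expect_true(redundancy_filter(random_dna(100), character(0)))
})

test_that("short candidates cannot contain a 40 bp match", {
  set.seed(1)
  s <- random_dna(200)
  expect_true(redundancy_filter(substr(s, 1, 39), s))
})

test_that("an exact 40 bp shared substring is rejected", {
  set.seed(2)
  collected <- random_dna(200)
  cand <- paste0(random_dna(30), substr(collected, 50, 89), random_dna(30))
  expect_false(redundancy_filter(cand, collected))
})

test_that("a reverse-complement 40 bp match is rejected", {
  set.seed(3)
  collected <- random_dna(200)
  sub <- substr(collected, 101, 140)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub)))
  cand <- paste0(random_dna(25), rc, random_dna(25))
  expect_false(redundancy_filter(cand, collected))
})

mutate_at <- function(s, at) {
  v <- strsplit(s, "")[[1]]
  for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  paste(v, collapse = "")
}

test_that("identity exactly 90% is accepted, just above is rejected", {
  set.seed(4)
  for (rep in 1:10) {
    collected <- random_dna(60)
    window <- substr(collected, 11, 50)
    # 4 mismatches -> 36/40 = 90% exactly: accept
    cand36 <- paste0(random_dna(10), mutate_at(window, c(5, 15, 25, 35)),
                     random_dna(10))
    # 3 mismatches -> 37/40 > 90%: reject
    cand37 <- paste0(random_dna(10), mutate_at(window, c(5, 15, 25)),
                     random_dna(10))
    expect_identical(redundancy_filter(cand36, collected),
                     !oracle_redundant(cand36, collected))
    expect_identical(redundancy_filter(cand37, collected),
                     !oracle_redundant(cand37, collected))
    expect_false(redundancy_filter(cand37, collected))
    if (oracle_best_window_matches(cand36, collected) == 36L &&
        !oracle_redundant(cand36, collected))
      expect_true(redundancy_filter(cand36, collected))
  }
})

test_that("screen agrees with the all-windows oracle on random toys", {
  set.seed(5)
  for (rep in 1:30) {
    collected <- replicate(2, random_dna(sample(45:90, 1)))
    cand <- if (rep %% 3 == 0) {
      src <- collected[[1]]
      k <- sample(0:5, 1)
      paste0(random_dna(8),
             mutate_at(substr(src, 3, 44), sample(42, k)), random_dna(8))
    } else random_dna(sample(45:90, 1))
    expect_identical(redundancy_filter(cand, collected),
                     !oracle_redundant(cand, collected),
                     info = paste("rep", rep))
  }
})

test_that("N never counts as a match", {
  set.seed(6)
  collected <- random_dna(80)
  cand <- substr(collected, 21, 60)
  expect_false(redundancy_filter(cand, collected))
  v <- strsplit(cand, "")[[1]]
  v[c(5, 15, 25, 35)] <- "N"              # 36 true matches left
  expect_true(redundancy_filter(paste(v, collapse = ""), collected))
})

test_that("design output is deterministic, byte-identical BED", {
  g <- small_genome()
  d1 <- small_design(g)
  d2 <- small_design(g)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  export_targets_bed(d1, f1); export_targets_bed(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_targets_bed(f1)
  expect_equal(length(back), length(d1$targets))
  expect_equal(start(back), start(sort(d1$targets, ignore.strand = TRUE)))
})

test_that("design respects per-gene caps, minimum lengths and budget", {
  g <- small_genome()
  budget <- 18000
  d <- design_targets(g, design_config(
    n_genomewide_genes = 20L, total_bp_budget = budget,
    candidate_gene_ids = g$candidate_ids), seed = 11)
  t <- d$targets
  noncand <- t[!t$role %in% "candidate_gene"]
  expect_true(all(width(noncand) >= 40L |
                    noncand$role == "long_first_exon_end"))
  per_gene <- tapply(width(noncand), noncand$gene_id, sum)
  max_exon <- max(width(g$exons))
  expect_true(all(per_gene <= 1500 + max_exon))
  expect_lte(d$total_bp, budget + 1500 + max_exon)
  expect_equal(d$total_bp, sum(width(t)))
  # within-gene targets never overlap
  by_gene <- split(t, t$gene_id)
  expect_true(all(vapply(by_gene, function(x)
    length(GenomicRanges::reduce(x, ignore.strand = TRUE)) == length(x),
    TRUE)))
})

test_that("no two emitted targets share a >90% 40 bp window", {
  g <- generate_reference(genome_spec(60000L, 8L, n_candidate_genes = 2L,
                                      seed = 21))
  d <- design_targets(g, design_config(
    n_genomewide_genes = 5L, total_bp_budget = 15000,
    candidate_gene_ids = g$candidate_ids), seed = 3)
  t <- sort(d$targets, ignore.strand = TRUE)
  expect_lte(length(t), 50)
  seqs <- as.character(Biostrings::extractAt(
    g$seqs[[1]], IRanges(start(t), end(t))))
  for (i in seq_along(seqs)) {
    expect_false(oracle_redundant(seqs[i], seqs[-i]),
                 info = paste("target", i))
  }
})

test_that("candidate-only design returns exactly those genes' exons", {
  g <- small_genome()
  ids <- g$candidate_ids[1:2]
  d <- design_targets(g, design_config(
    n_genomewide_genes = 0L, total_bp_budget = 1e6,
    candidate_gene_ids = ids), seed = 1)
  expect_setequal(unique(d$targets$gene_id), ids)
  n_exp <- sum(g$exons$gene_id %in% ids)
  # all exons present unless screened for redundancy
  expect_equal(length(d$targets) + d$n_rejected_redundant, n_exp)
})

test_that("a budget below the candidate footprint errors", {
  g <- small_genome()
  expect_error(design_targets(g, design_config(
    n_genomewide_genes = 0L, total_bp_budget = 100,
    candidate_gene_ids = g$candidate_ids), seed = 1), "budget")
})

test_that("every chromosome receives genome-wide genes when available", {
  g <- small_genome()
  d <- small_design(g)
  gw <- unique(d$targets$gene_id[!d$targets$gene_id %in% g$candidate_ids])
  chroms <- unique(as.character(seqnames(
    g$genes[g$genes$gene_id %in% gw])))
  expect_setequal(chroms, names(g$seqs))
})
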