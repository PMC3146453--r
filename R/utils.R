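#' @import data.table
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code for an unordered diploid genotype over {A,C,G,T}
IUPAC_DIPLOID <- c(
  "AA" = "A", "CC" = "C", "GG" = "G", "TT" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W",
  "CG" = "S", "CT" = "Y", "GT" = "K"
)
IUPAC_ALLELES <- c(
  A = "AA", C = "CC", G = "GG", T = "TT",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT"
)

#' Diploid genotype to IUPAC code
#'
#' @param a,b Single-character alleles over A/C/G/T.
#' @return IUPAC single-letter genotype code (ambiguity code when `a != b`).
#' @export
genotype_to_iupac <- function(a, b) {
  key <- ifelse(a <= b, paste0(a, b), paste0(b, a))
  out <- IUPAC_DIPLOID[key]
  if (anyNA(out)) stop("alleles must be A, C, G or T")
  unname(out)
}

#' IUPAC genotype code to allele pair
#'
#' @param code IUPAC single-letter genotype code (A/C/G/T or M/R/W/S/Y/K).
#' @return Character matrix with two columns, one row per code.
#' @export
iupac_to_alleles <- function(code) {
  key <- IUPAC_ALLELES[toupper(code)]
  if (anyNA(key)) stop("malformed IUPAC genotype code: ",
                       paste(unique(code[is.na(key)]), collapse = ", "))
  matrix(c(substr(key, 1, 1), substr(key, 2, 2)), ncol = 2,
         dimnames = list(NULL, c("a1", "a2")))
}

is_het_code <- function(code) toupper(code) %in% c("M", "R", "W", "S", "Y", "K")

# round half away from zero, the convention used in all reported percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

phred_to_error <- function(q) 10^(-q / 10)

error_to_phred <- function(e, qmin = 2, qmax = 41) {
  q <- ifelse(e <= 0, Inf, -10 * log10(e))
  pmin(pmax(round_half_up(q), qmin), qmax)
}

qual_string_to_int <- function(qual) {
  lapply(qual, function(s) as.integer(charToRaw(s)) - 33L)
}

qual_sum <- function(qual) {
  vapply(qual, function(s) sum(as.integer(charToRaw(s))) - 33L * nchar(s), 0L)
}

# Deterministic child seed so adding a pipeline stage never perturbs the
# draws of an earlier one. Plain 31-bit LCG-style mix of seed and tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% (2^31 - 2) + 1)
}

# largest-remainder (Hamilton) apportionment of `total` among weights;
# ties in the remainder go to the earlier index
apportion_largest_remainder <- function(weights, total) {
  stopifnot(all(weights > 0), total >= 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# complement of a set of 1-based closed intervals in [1, len];
# intervals are merged first so overlaps are tolerated
interval_gaps <- function(starts, ends, len) {
  if (length(starts) == 0) return(data.frame(start = 1L, end = as.integer(len)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  if (length(starts) > 1) {
    ms <- integer(0); me <- integer(0)
    cs <- starts[1]; ce <- ends[1]
    for (i in 2:length(starts)) {
      if (starts[i] <= ce + 1L) ce <- max(ce, ends[i])
      else { ms <- c(ms, cs); me <- c(me, ce); cs <- starts[i]; ce <- ends[i] }
    }
    ms <- c(ms, cs); me <- c(me, ce)
  }
  gs <- c(1L, me + 1L)
  ge <- c(ms - 1L, as.integer(len))
  keep <- gs <= ge
  data.frame(start = as.integer(gs[keep]), end = as.integer(ge[keep]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
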