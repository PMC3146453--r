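# Sequence-redundancy screen for capture design: a candidate exon is
# rejected when any ungapped window of `window` bp aligned against an
# already-collected exon (either strand) shows identity strictly greater
# than `identity`. Implemented as exact seed-and-extend: a window of 40 bp
# with <= 3 mismatches must contain an exact match run of at least
# ceil(37/4) = 10 bp, so 10-mer seeds lose no qualifying window.

REDUNDANCY_SEED_K <- 10L

encode_base_codes <- function(seq) {
  raw <- as.integer(charToRaw(toupper(seq)))
  code <- integer(256)
  code[as.integer(charToRaw("ACGT"))] <- 1:4
  code[raw]
}

encode_kmers <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  val <- as.numeric(codes[1:m]) - 1
  ok <- codes[1:m] > 0L
  for (t in 2:k) {
    val <- val * 4 + (codes[t:(m + t - 1L)] - 1)
    ok <- ok & codes[t:(m + t - 1L)] > 0L
  }
  val[!ok] <- NA_real_
  val
}

# any ungapped window of `window` aligned positions between a and b with
# at least `thr` matches? N (or any non-ACGT) never counts as a match.
has_window_match <- function(codes_a, codes_b, window, thr) {
  na <- length(codes_a); nb <- length(codes_b)
  if (na < window || nb < window) return(FALSE)
  k <- REDUNDANCY_SEED_K
  ka <- encode_kmers(codes_a, k)
  kb <- encode_kmers(codes_b, k)
  da <- data.table::data.table(val = ka, i = seq_along(ka))[!is.na(val)]
  db <- data.table::data.table(val = kb, j = seq_along(kb))[!is.na(val)]
  if (nrow(da) == 0 || nrow(db) == 0) return(FALSE)
  hits <- db[da, on = "val", nomatch = 0L, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(FALSE)
  for (d in unique(hits$i - hits$j)) {       # align a[i] with b[i - d]
    lo <- max(1L, 1L + d)
    hi <- min(na, nb + d)
    len <- hi - lo + 1L
    if (len < window) next
    av <- codes_a[lo:hi]
    bv <- codes_b[(lo - d):(hi - d)]
    match <- as.integer(av == bv & av > 0L)
    cs <- cumsum(match)
    wsum <- cs[window:len] - c(0L, cs[seq_len(len - window)])
    if (any(wsum >= thr)) return(TRUE)
  }
  FALSE
}

#' Redundancy screen for a candidate capture sequence
#'
#' Accepts the candidate unless some ungapped window of exactly
#' `window` bp, aligned against any already-collected sequence on either
#' strand, shows identity strictly greater than `identity` (at the
#' defaults, 37 or more matches out of 40). Candidates shorter than the
#' window are always accepted. `N` never counts as a match.
#'
#' @param candidate_sequence Character scalar, uppercase DNA over
#'   A/C/G/T/N.
#' @param collected_sequences Character vector (or list) of previously
#'   accepted sequences.
#' @param window Window length in bp (default 40).
#' @param identity Identity fraction that must be strictly exceeded for
#'   rejection (default 0.90).
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
redundancy_filter <- function(candidate_sequence, collected_sequences,
                              window = 40L, identity = 0.90) {
  stopifnot(length(candidate_sequence) == 1, window >= 1,
            identity > 0, identity < 1)
  collected_sequences <- as.character(unlist(collected_sequences))
  if (length(collected_sequences) == 0) return(TRUE)
  if (nchar(candidate_sequence) < window) return(TRUE)
  thr <- floor(identity * window + 1e-9) + 1L
  fwd <- encode_base_codes(candidate_sequence)
  rev <- encode_base_codes(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(candidate_sequence))))
  for (s in collected_sequences) {
    if (nchar(s) < window) next
    cb <- encode_base_codes(s)
    if (has_window_match(fwd, cb, window, thr)) return(FALSE)
    if (has_window_match(rev, cb, window, thr)) return(FALSE)
  }
  TRUE
}
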