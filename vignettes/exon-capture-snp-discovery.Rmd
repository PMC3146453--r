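---
title: "Exon capture design and cross-species SNP discovery with excapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon capture design and cross-species SNP discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excapr)
```

# The problem

Targeted exon capture enriches fragmented genomic DNA for a designed set
of exon sequences before short-read sequencing. It allows gene-targeted,
genome-wide SNP discovery in species with no genome resources of their
own, by designing the capture against the reference genome of a related,
well-studied species. The computational workflow that `excapr`
implements has five stages: capture target design, mapped-read
filtering, empirical base-quality recalibration, diploid consensus
genotyping, and variant classification with quality-control summaries.
The package also ships a seeded simulator so the full pipeline can be
exercised against a known truth set.

# Target design

The design balances three goals: always include a small panel of named
candidate genes in full; spread the remaining sampling evenly across the
genome; and keep the total bases near a budget (defaults: 1,500 exon bp
per gene, roughly 3 Mb overall at full scale).

Genome-wide sampling visits chromosomes round-robin. Visit counts per
chromosome are fixed up front by largest-remainder apportionment of the
requested gene count, proportional to chromosome length — a
deterministic reading of "proportionally more visits for longer
chromosomes" chosen for testability over a stochastic round-robin. On
each visit the selected gene is the one whose midpoint lies closest to
the midpoint of the largest contiguous span of the chromosome free of
previously selected gene footprints, which spreads picks apart
geometrically. Ties (equal-length spans; equidistant genes) break toward
the lower genomic coordinate, so the whole design is a pure function of
annotation, configuration and seed.

Per gene, the exon containing the 5' UTR is always collected (the first
exon in transcription order — the highest-coordinate exon for
minus-strand genes); remaining exons of at least `min_exon_bp` (40 bp)
are drawn uniformly without replacement until the running total first
exceeds `per_gene_bp_cap` (1,500 bp). The crossing exon is kept: the
reading of "sample until adding an exon brings the total above the cap"
that retains the final draw. A gene whose every exon exceeds the cap
contributes `long_first_exon_end_bp` (750 bp) from each end of its 5'
terminal exon instead. Two deliberate interpretations, flagged here
because the design rules are silent on them: the 40 bp minimum applies
to *all* non-candidate exons including the UTR exon, and the redundancy
screen applies to candidate-gene exons as well as genome-wide ones
(screening in emission order, candidates first).

The redundancy screen rejects a candidate sequence if any ungapped
window of exactly 40 aligned bp against an already-collected sequence,
on either strand, exceeds 90% identity — at the defaults, 37 or more
matches out of 40, with `N` never matching. It is implemented as exact
seed-and-extend rather than a heuristic aligner: a 40 bp window with at
most 3 mismatches must contain an exact run of at least
`ceil(37/4) = 10` bases, so 10-mer seeds followed by full diagonal
scoring cannot miss a qualifying window. The contract is the
window-identity rule itself, and the test suite checks it against a
brute-force all-offsets oracle.

Coordinates are 1-based closed internally, following the
IRanges/GenomicRanges convention the implementation is built on; BED
output is converted to its 0-based half-open convention by the exporter
and reports are 1-based.

# Read filtering

Reads must be uniquely mapped and on target. Unique is operationalized
as MAPQ above a threshold (default MAPQ > 0) since mapper-internal
uniqueness flags are not portable; on target means at least one aligned
base overlaps a designed exon. PCR duplicates are groups of reads
identical in (chromosome, leftmost position, strand) — with fixed-length
ungapped single-end reads this equals full-span identity — and only the
read with the highest sum of base qualities survives, ties broken toward
the lexicographically smallest read id so the result is independent of
input order. Reads with indel-containing CIGARs are skipped with a
warning; indel handling is out of scope throughout.

# Base-quality recalibration

Early-generation sequencers could report poorly calibrated quality
scores. The empirical correction bins every filtered, on-target,
duplicate-free aligned base by its reported quality `q` and treats every
mismatch against the reference as sequencer error. The error rate is
implemented literally as the ratio of mismatches to matches,
`e(q) = m(q)/M(q)` — not `m/(m+M)`; the two differ by O(e²) and the
ratio form is the package's contract (`rate_denominator = "aligned"`
switches it). The replacement quality is `round(-10*log10(e))`, rounded
half-up and clamped to [2, 41] (the realistic reported-quality range; a
bin with zero mismatches gets 41, a bin with zero matches gets 2).
Qualities present in reads but absent from the table map to the nearest
observed bin (ties toward the lower score).

Treating all mismatches as error is deliberately conservative: for an
individual diverged from the reference, real differences inflate `e(q)`
and depress the replacement qualities. `average_tables()` exists for
exactly that case — the per-bin arithmetic mean of error rates across
samples (over the samples in which the bin was observed) lets a diverged
sample borrow the calibration of conspecific samples sequenced on the
same platform. The test suite verifies the direction of both effects.
Known-variant masking is intentionally off by default, matching the
all-mismatches-are-error definition.

# Consensus genotyping

The caller computes, per covered target position, a posterior over the
10 unordered diploid genotypes, treating base calls as independent draws
given the genotype: a base matching allele `x` has probability `1 - e`
under a genotype containing `x` and `e/3` otherwise, averaged over the
two alleles, with `e` from the (recalibrated) Phred quality. This
independent-error model is a deliberate simplification of
mapper-specific consensus models with error-dependency corrections; the
depth/quality acceptance thresholds, not any particular mapper's
internals, define the contract.

The prior has three levels: `1 - het_prior - hom_prior` on the reference
homozygote, `het_prior/3` on each of the three heterozygotes carrying
the reference allele, and `hom_prior/6` on the six remaining genotypes.
`het_prior` defaults to 0.001, the conventional per-site heterozygosity
scale; `hom_prior` defaults to `het_prior` because in the cross-species
setting the fixed-difference rate is of the same order as
heterozygosity. Sweeping both together (`theta` in
`simulate_study()`) probes call-set stability against this prior, the
analogue of sweeping a mapper's assumed mutation rate.

Numerical choices: likelihoods accumulate in log space; the posterior
complement `1 - p` is computed as a ratio of exponentials relative to
the row maximum (no catastrophic cancellation); consensus quality is
rounded half-up and capped at 99; exact posterior ties break first
toward a genotype containing the reference allele, then alphabetically.
Depth-0 columns produce no call; reference-`N` positions and non-ACGT
read bases are dropped. For depths up to 6 the suite checks genotype
*and* quality against an independent exhaustive enumeration in plain
probability arithmetic.

A property of this model worth knowing: discriminating a homozygous
non-reference site from a heterozygote gains only ~3 Phred per
concordant read (the likelihood ratio per base is about 2), so with the
8x / Q30 thresholds a fixed difference becomes callable at roughly 12x.
Variant counts are therefore compared at *callable* positions, the same
conditioning the "genotyped bases" denominator applies.

# Variant classification and summaries

High-confidence calls equal to the reference are dropped; single-base
calls differing from the reference are fixed differences; ambiguity
codes are heterozygous SNPs (a heterozygote with two non-reference
alleles counts once, contributing both reference-to-alternate
substitutions at half weight to Ts/Tv). Percentages are rounded half-up
to two decimals; overlap fractions to whole percents. One quirk
surfaced by the packaged per-individual count table: one published
percentage cell (3,854/2,306,566 printed as 0.16%) was evidently
truncated rather than rounded — half-up rounding gives 0.17 — while
every other cell matches half-up rounding exactly; the package keeps the
single consistent rule and the acceptance check compares that cell to
one unit in the final printed decimal.

Known-variant concordance counts a position match when a called variant
sits at a known-variant position (same 1-based coordinates — no
coordinate-convention heuristics are applied) and an allele mismatch
when the genotype's allele set is disjoint from the known alleles.
Sanger verification compares IUPAC genotypes case-insensitively:
concordant records have pipeline genotype equal to the Sanger genotype
(and variant relative to the reference); false positives are pipeline
variants where Sanger equals the reference. Genotype equality, not
allele compatibility, is the implemented criterion — it reproduces the
packaged verification fixture's counts exactly (19/12/4 concordant,
0/0/5 false positives).

# What the simulator emulates — and what it does not

The generator produces multi-chromosome genomes with non-overlapping
gene models at a requested GC content, individuals with homozygous
substitutions at `divergence_rate` and heterozygous sites at
`heterozygosity_rate` (defaults 0.005 and 0.001: the observed scale for
a wild congener diverged one to two million years from the reference
species, and typical outbred-mammal heterozygosity), and 36 bp
single-end libraries with per-quality error rates, an off-target
fraction (default 0.75, matching observed on-target fractions of
20–29%), and PCR duplicates. Edited sites are drawn without replacement
so a site is never both fixed and heterozygous — the simplest contract
that keeps the truth set unambiguous. Reads carry their true origin, so
mapping is bypassed: MAPQ 60 for unique placement, with a configurable
fraction flagged MAPQ 0 purely to exercise the uniqueness filter. Every
stage draws its own child seed derived from the master seed, so adding a
stage never perturbs earlier draws.

Deliberate omissions, which bound what passing tests show about real
data: no indels or structural variants, no paired-end reads, no
cycle- or context-dependent error profiles, no per-probe
capture-efficiency model, no mapping ambiguity (real divergent reads
mismap; simulated ones cannot), and alternate alleles drawn uniformly —
so simulated data has Ts/Tv ≈ 0.5 rather than the ~3 of real mammalian
variation, and Ts/Tv-based QC can only be checked against injected
mixtures, not against realistic values.

# Problem sizes and reproducibility

`simulate_study()` fixes the package's reference end-to-end conditions:
a 1 Mb genome in two chromosomes, ~60 genes with a 10-gene candidate
panel and 40 genome-wide genes (roughly 55–65 kb of targets), 20x mean
on-target depth, 10% duplicates, all-Q30 reads with true error 0.001,
and the prior sweep θ ∈ {0.001, 0.004, 0.007}. These sizes give a few
hundred truth variants over the targets — enough for 3-standard-
deviation binomial recovery checks — while a full run stays within a few
minutes on one CPU. At 20x, duplicate-removal statistics exceed the
injected 10% because independent fragments also collide at the same
(position, strand) by chance; the removed fraction is the sum of both
effects, which is what the statistic means operationally.

Determinism is end to end: identical seeds give byte-identical FASTA,
BED and call tables, and `scripts/acceptance.R --seed N` reproduces
every reported number.

# Known limitations

* The genotype quality scale is model-specific; numeric agreement with
  any particular legacy caller's consensus qualities is not a contract,
  only the 8x / Q30 accept/reject behavior is.
* The redundancy screen is exact for the 40 bp / >90% rule but is not a
  general aligner; gapped similarity is invisible to it, as it was to
  the rule it implements.
* `filter_reads()` requires coordinate-sorted input and streams no
  chunks; genomes far beyond the tested scale would need external
  sorting and chunked pileups.
* Diploid calls are assumed everywhere, including sex chromosomes (the
  emulated study design sequenced females only).
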