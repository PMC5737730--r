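---
title: "Single-pass comprehensive variant detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-pass comprehensive variant detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`omnivar` detects SNVs, indels, structural variants (SVs: deletions, tandem
duplications, inversions, translocations) and read-depth copy-number
variants from a coordinate-sorted BAM of paired-end short reads. All
evidence classes are collected in one pass over each chromosome: per-base
allele counts, physical coverage, soft-clip and split-read boundaries, and
discordant read pairs. The stages are:

1. **Insert-size model** — concordance thresholds from a sample of pairs.
2. **Evidence scan** — per-base accumulators and weighted breakpoint
   candidates.
3. **Clustering** — candidates grouped per reference base by variant type
   and implied length, under an adaptive tolerance.
4. **Significance** — every cluster and SNV scored with a binomial
   mismapping probability.
5. **Matching** — start and end breakpoints paired into typed calls;
   translocations matched genome-wide after all chromosomes.
6. **Read-depth CNV** — a windowed depth profile segmented after GC
   correction.

# The insert-size model

Insert-size distributions of real libraries are right-skewed, so thresholds
are rank-based rather than moment-based. From a sample of pairs (default up
to $10^7$; template lengths of same-chromosome pairs, one per pair,
preferring aligner-marked proper pairs so that SV-spanning fragments do not
contaminate the upper tail), values above five times the median are removed
as outliers, and

$$i_{\min} = Q(\Phi(-3)), \qquad i_{\max} = Q(\Phi(3))$$

are the empirical quantiles at the normal three-sigma tail levels
(0.00135 / 0.99865), with linear interpolation between order statistics
(R's type-7 rule; the choice of interpolation moves thresholds by less than
one base at realistic sample sizes). A pair is *concordant* when it is
FR-oriented on one chromosome with insert in $[i_{\min}, i_{\max}]$.
Everything else is typed by its geometry: too-large inserts indicate a
deletion, too-small inserts are kept as insertion-type evidence (a
documented choice; abnormally small inserts are also produced by
short-fragment artifacts), RF (outward) orientation a tandem duplication,
FF/RR an inversion, and cross-chromosome mates a translocation. Bimodal
insert distributions are flagged with a warning (density dip check at the
median versus the quartiles); mixed libraries should be run separately.

Single-end input disables all pair-based stages; SNVs, within-read indels
and read-depth CNVs remain available. Within-read indel clustering then
uses a tight internal fallback tolerance (30 bases at one read), since
CIGAR-derived lengths are near-exact. For variable-length libraries the
modal read length is used as $L_r$.

# Evidence collection

**Physical depth.** The depth $n$ at a base counts fragments, not sequenced
bases: aligned spans of all mapped records (a split read's supplementary
segment covers reference that its primary does not, so supplementary spans
are included), the unsequenced gap between the mates of a concordant pair,
and the potential-breakpoint extents of discordant pairs and clipped reads.
This physical coverage is what the binomial model conditions on.

**Breakpoint candidates.** Each read contributes weighted candidates:

* A CIGAR deletion of length $k$ at position $p$: one start candidate at
  $p$ and one end candidate at $p+k$ (weight 1). An insertion: a single
  candidate at the insertion point.
* A split read (primary + supplementary via the `SA` tag, each mapped
  segment at least 20 bases): candidates at the two query-inner reference
  edges, typed by the relative placement and orientation of the segments
  (colinear gap = deletion; reversed order = duplication; opposite strand =
  inversion; different chromosome = translocation breakends).
* A discordant pair: the breakpoint is not observed directly, so a
  candidate is recorded at *every* base at which a breakpoint would let the
  fragment form a concordant insert — a window of width $i_{\max}-i_{\min}$
  adjacent to the read, clamped at the mate. All candidates of one read
  share the implied length: `insert − i_median` (deletion),
  `i_median − insert` (small-insert/insertion),
  `insert + i_median − 2L_r` (tandem duplication), and the difference of
  the two reads' start positions (inversion). For translocations each
  candidate instead carries an implied mate-junction position, computed by
  assuming a median-length fragment.
* Soft-clips of at least 5 bases mark a boundary base. When a boundary
  falls inside a discordant read's window, the candidate at the boundary
  keeps weight 1.0 and the rest of that window is half-weighted (0.5).
  With several boundaries in one window, each anchored base keeps full
  weight. This anchoring yields base-resolution breakpoints while a single
  aberrant clipped read cannot override the bulk of the evidence.

Reads with MAPQ below 1 count toward depth but contribute no candidates
and no SNV evidence; they cannot be distinguished from mismappings.

**Duplicate filtering (optional, on by default).** Pairs sharing
orientation and external mapping coordinates are duplicates; the pair with
the highest summed MAPQ is kept (ties: first encountered). The read's own
external coordinate is soft-clip adjusted; the mate's is taken as stored,
which keeps the key computable in a single pass. Cross-chromosome pairs are
eligible. Only the record-level mapping quality is available in one pass,
so the "pair MAPQ" is the canonical record's MAPQ when the mate's is
unknown.

# Clustering by type and length

Two overlapping events (for instance two heterozygous deletions of similar
size) can leave superimposed evidence at nearby bases, so candidates at
each (position, side, type) are clustered by implied length. A candidate
with length $L$ joins an existing cluster with running mean $L_{bc}$ and
weighted support $x_{bc}$ when

$$|L_{bc} - L| \le (i_{\max} - i_{\min} + i_{median} - 2L_r)
  \left(1 + \frac{1}{x_{bc}}\right).$$

A single supporting read is a poor length estimate — with the base term at
500 bases, a second read may differ by 1000 — and the tolerance tightens
toward the base term as support accumulates. Among eligible clusters the
one with the most support wins; remaining ties are broken by the smallest
length difference, then the oldest cluster (a documented completion: the
greedy rule needs a deterministic order). A cluster never counts the same
read twice. Candidates are processed exact-evidence first (CIGAR/split
candidates before windowed ones), then in input order; greedy clustering is
order-sensitive, so the order is fixed and documented. Translocation
candidates carry no length; they are clustered on the implied mate-junction
position with the same tolerance.

For well-separated evidence (length spread within the base term) the greedy
result provably collapses to a single weighted mean, which the
implementation uses as a fast path; the unit tests verify exact equivalence
against an exhaustive simulation of the rules.

A documented consequence of the tolerance: within-read indel evidence with
lengths 2 and 3 at the same base merges into one cluster (the tolerance is
never smaller than the base term, which is hundreds of bases for typical
libraries). Distinct co-located indels are only separated when their
lengths differ by more than the base term.

# The binomial mismapping probability

The mapping-quality threshold $m$ (default 20) defines a per-read
mismapping probability $p = 10^{-m/10}$. For a cluster with rounded support
$x$ at physical depth $n$,

$$p_{bc} = \Pr(X \ge x) = 1 - \sum_{k=0}^{x-1} \binom{n}{k} p^k q^{n-k},
\qquad q = 1 - p,$$

the probability that all supporting reads are mismapped. The implementation
sums the upper tail directly in log space — the printed complementary form
loses all precision below $10^{-16}$ — and precomputes tables up to
$n_{\max} = 1000$ (rebuilt automatically for non-default $m$, cached with a
header and checksum); deeper positions fall through to direct computation.
Fractional (half-weighted) support is rounded half-up, matching the integer
tables. Calls require $p_{bc} \le \alpha$; $\alpha$ defaults to $10^{-5}$,
a genome-wide-multiplicity choice that is exposed as a parameter because no
canonical value exists for it.

SNVs use the same machinery: each base with alternate-allele observations
is scored with its alt count against the physical depth. Additional SNV
filters default to mean alt base quality ≥ 20, mean alt MAPQ ≥ $m$, alt
count ≥ 3, with per-base inclusion at base quality ≥ 13. These filter
values are package choices — deliberately conservative, conventional
short-read values — and are all configurable; the genotype field is a
simple allele-fraction heuristic (alt fraction ≥ 0.8 of sequenced reads is
reported 1/1) and must not be read as a genotype likelihood.

# Breakpoint matching

After a chromosome is processed, significant clusters are reduced by
non-maximum suppression: per (chromosome, type, side), clusters are grouped
into regions separated by more than $i_{\max}-i_{\min}$, and the
highest-support cluster per region is kept (anchored clusters win ties).
Clusters whose length differs from the winner by more than the base term
are treated as distinct co-located events and kept by the same rule. This
step is a documented completion of the published matching stage: windowed
candidates otherwise leave hundreds of satellite clusters around each true
breakpoint, and the half-weighting already designates the anchored base as
the breakpoint estimate.

A start cluster $B_s$ with mean length $L_s$ and an end cluster $B_e$ with
mean length $L_e$ (same chromosome and type) are matched when **both**

$$|B_s + L_s - B_e| \le c\,(i_{\max}-i_{\min}), \qquad
  |B_e - L_e - B_s| \le c\,(i_{\max}-i_{\min}), \qquad c = \tfrac38,$$

hold. Matching is greedy by descending combined support and each cluster is
used at most once. Translocations are matched after all chromosomes with
the analogous conditions on the mean mate positions,
$|M_s - B_e| \le c\,(i_{\max}-i_{\min})$ and
$|M_e - B_s| \le c\,(i_{\max}-i_{\min})$, and emitted as breakend pairs.

The reported SV length is the span $B_e - B_s$ when both breakpoints are
clip/split-anchored — anchored breakpoints are base-resolved, so the span
is the best estimate — otherwise the mean of $L_s$, $L_e$ and the span,
which folds in the independent insert-size information. Indels (< 50
bases, the conventional indel/SV boundary) are matched with a ±2-base
window, the resolution at which short indels are benchmarked; insertions
are single-locus calls. Insertions longer than a read are only observable
as clip and small-insert evidence and are reported with an imprecise
length.

# Read-depth CNV detection

The depth-based caller is a deliberately transparent windowed method: mean
physical depth in fixed 100-base windows, GC-corrected by median ratio in
1% GC bins (bins under 20 windows borrow the nearest populated bin, all-N
windows are dropped), then runs of at least 5 consecutive windows below
0.6× or above 1.4× the genome-median depth become deletion or duplication
calls with a robust z-score. All four parameters are exposed. Paired-end SV
calls and depth CNV calls for the same event are both emitted; they are
complementary evidence, and no attempt is made to merge them.

# The simulator

Every stage is testable without external data through a bundled simulator.
It generates a random genome (per-kilobase GC drawn from a stated range),
plants variants on a diploid sample (homozygous on both haplotypes,
heterozygous on one), draws fragments with normal inserts, and synthesizes
idealized alignments back to the reference: within-read I/D CIGARs across
short indels, soft-clips and supplementary split alignments (with `SA`
tags) at SV junctions, discordant orientations and template lengths for
SV-spanning fragments, and aligner-style proper-pair flags (FR, insert
within 4 SD of the library mean). Duplicate fragments are added at a stated
rate. Identical spec and seed give identical output.

What the simulator deliberately does **not** model: mismapping and
repeat-induced ambiguity (MAPQ is constant 60), base-quality decay and
indel sequencing errors (substitutions only, uniform rate, constant Q30),
chimeric artifacts, and reference N-gaps. Passing the bundled end-to-end
tests therefore demonstrates that the algorithm recovers what its evidence
model describes under clean mapping; it does not demonstrate robustness to
alignment artifacts in real data, where the binomial mismapping model and
the MAPQ gates carry that burden.

The standard evaluation scenario (`mixed_scenario_spec()`) is a 1 Mb
diploid genome at 30× coverage, 150-base reads, inserts Normal(500, 50),
0.1% substitution error and 5% duplicates, carrying 100 SNVs, 20 indels of
2–40 bases, deletions/duplications/inversions of 300, 1000 and 5000 bases
in mixed zygosity, and one reciprocal translocation. These sizes keep a
full run (simulation plus calling) around a minute on one CPU while giving
every variant class dozens of supporting fragments; unit tests use 60–100
kb genomes with the same library parameters.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; VCF output converts to the
  1-based anchor-base convention. Deletions under 50 bases are written with
  explicit alleles, larger events as symbolic ALTs with `END`/`SVLEN`,
  translocations as `BND` pairs annotated with `CHR2`/`POS2`/`MATEID`.
* A constant insert library degenerates to
  $i_{\min}=i_{median}=i_{\max}$; pairs are then concordant only at exactly
  that insert. All-outlier insert samples, empty window sets and all-N
  windows are hard errors rather than silent zeros.
* Support is clamped to depth (with a warning) before scoring; it indicates
  a depth-accounting inconsistency and is not expected on well-formed
  input.
* Tail probabilities at `x = 0` are exactly 1 and at `x > n` exactly 0;
  probabilities are clipped to [0, 1] after summation.

# Known limitations

* Greedy clustering and greedy matching are order-dependent heuristics; no
  globally optimal assignment is attempted.
* Insertions between the read length and the insert size are detected but
  their length is not estimable from short-read evidence alone.
* The duplicate filter cannot see the mate's soft-clipping (single-pass
  constraint), so a duplicate pair whose two copies differ only by mate
  clipping is kept.
* The read-depth CNV caller is a simple windowed segmentation; it has no
  breakpoint refinement and its calls are `IMPRECISE` by construction.
* Multi-segment (three or more parts) split reads use only the first
  supplementary segment.
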