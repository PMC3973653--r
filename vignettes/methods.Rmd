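---
title: "Methods: small-RNA profiling, target rules and secondary siRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling, target rules and secondary siRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canesrna)
```

## Scope and model of the data

`canesrna` analyses bulk small-RNA sequencing libraries from plants — the
motivating design is four pooled leaf libraries from drought-tolerant and
drought-sensitive sugarcane cultivars at 0 h and 24 h of water depletion,
optionally augmented by individual-cultivar libraries. Because sugarcane
lacks an assembled genome, every stage is defined over explicit sequence
rules (exact or bounded-mismatch string matching) rather than genome
alignment, which makes the whole chain deterministic and auditable. All
sequences are held in a single DNA alphabet (U mapped to T) so that reads,
mature-miRNA references, transcripts and repeats compare directly; all
coordinates are 1-based inclusive on the forward strand of the named
reference, with antisense alignments printed high→low (`157-139`).

## Preprocessing

Raw reads pass a fixed filter order: adapter/N trimming → length window →
low-complexity filter → contaminant removal → collapsing. The order
matters only for the attrition bookkeeping (each stage count is ≤ the
previous); the surviving set is order-independent.

* **Adapter trimming** removes the 3′ adapter at its leftmost occurrence.
  Two occurrence types are recognised: the full adapter anywhere in the
  read, and an adapter *prefix* of ≥ 6 nt flush with the read's 3′ end
  (read-through into short inserts). Matching is exact; mismatch-tolerant
  trimming is deliberately out of scope — with exact matching the trimmed
  set is reproducible bit-for-bit and testable against planted truth.
  Reads still containing N are discarded.
* **Length window**: 18–28 nt inclusive. 17 and 29 nt reads fail; 18 and
  28 pass.
* **Low complexity**: a read needs ≥ 3 distinct bases. The test is
  invariant under reversal and complementation.
* **Contaminants** (t/rRNA, snoRNA): a read is removed iff it is an exact
  substring of a contaminant or of its reverse complement. Exact matching
  is the conservative choice; a mismatch-tolerant contaminant filter would
  need a tolerance the underlying databases do not define.

## Conserved-miRNA profiling and the electronic northern

Reads are compared ungapped and end-to-end against each reference mature
sequence of equal length and against equal-length windows of longer
references, with Hamming distance ≤ 3. The minimal-mismatch hit wins;
ties break to the lexicographically smallest reference id, and a read is
assigned to a single family only, so downstream count tests never
double-count. Variant labels (Roman numerals within a family, stars kept
as their own series) are assigned by sorting distinct mature sequences
lexicographically — labels are then independent of input order and
sequencing depth.

Expression is reported as raw counts and RPM = count × 10⁶ / library
total filtered reads (2 decimals in TSV output). Genome anchoring (the
option of additionally requiring a match in a related genome) is off by
default: it needs an external genome and adds nothing to the rule chain's
testability.

## Differential expression and concordance

With unreplicated pooled libraries, the appropriate per-sequence test is
the two-sided Fisher exact test on the 2×2 table
`[[count_a, total_a − count_a], [count_b, total_b − count_b]]`
(`stats::fisher.test`; the test suite cross-checks it against an
independent hypergeometric enumeration over all tables with the observed
margins). Within each library pair the m tested sequences get Bonferroni
control, `p_adj = min(1, p·m)`, significant at α = 0.05. Negative-binomial
or FDR-based machinery is a non-goal: there are no replicates to estimate
dispersion from.

The concordance classifier asks whether pooled libraries and individual
genotypes agree. Direction of change is the sign of an RPM ratio; zero
counts take a one-read pseudocount first (the data give no other
principled floor, and the pseudocount is disclosed in output). Comparison
1 contrasts the pooled genotype ratio under stress with the
individual-cultivar ratio. Comparison 2 is computed per genotype
(individual vs pooled control against stressed pool vs the same control)
and aggregated with OR — one agreeing genotype suffices, matching the
convention of marking entries that occur in only one genotype class as
positive. Classes: `both`, `comp1_only`, `comp2_only`, `neither`.

## Target prediction

Duplexes are strictly ungapped and full-miRNA-length: position *i* of the
miRNA (5′→3′) pairs with transcript position `offset + L − i`. Pair
states are WC, GU (G:U wobble) or MM. Numeric caps weight GU = 0.5;
adjacency rules treat any non-WC position as a mismatch position (the
convention of the established plant target-prediction tools). The six
acceptance rules are: total ≤ 4.0; no run of > 2 adjacent mismatch
positions; no adjacent mismatch positions within miRNA positions 2–12;
positions 10–11 both WC; ≤ 2.5 weighted mismatches over positions 1–12;
MFE ratio ≥ 0.74.

The energy model is an embedded nearest-neighbor stacking table: the ten
published Watson-Crick RNA/RNA stack parameters (expanded to all sixteen
dinucleotides by duplex symmetry), a simplified wobble treatment (−1.3
kcal/mol for a stack containing one G:U, −0.5 for tandem G:U), a stack
adjacent to an unpaired position contributing 0, and a flat +1.0 kcal/mol
penalty per unpaired position. This is intentionally not a full
secondary-structure folding engine: the acceptance rule consumes only the
*ratio* of two energies computed by the same function on the same
geometry, so the ratio is exactly 1 for the perfect complement by
construction and degrades smoothly with damage to the duplex. The
simplified wobble constants sit between the published wobble stack ranges;
their absolute accuracy matters much less than their monotonicity, and the
test suite pins the whole model against an independent table-lookup
recomputation. The cleavage coordinate is the transcript base paired to
miRNA position 10 (5′ side of the 10–11 bond) — standard slicer geometry.

Two details were genuinely open and decided here: (i) the published rule
list contains two rules both concerning positions around the duplex
centre; they are implemented separately (R3: adjacency in 2–12, R4:
10–11 perfect) and reported separately. (ii) Bulged duplexes are not
considered — the rule list never mentions gaps, and ungapped geometry
keeps the window scan exact.

## Secondary siRNA discovery

22-nt matched miRNAs are the trigger set. Each predicted target of a
trigger is scanned against the non-miRNA read pool: a read hits iff it
shares a contiguous exact match of ≥ 18 nt with the transcript (sense) or
its reverse complement. Hits whose start and end each differ by ≤ 2 nt on
the same strand merge transitively into a candidate; the representative is
the member with the maximal summed count (ties: lexicographically smallest
sequence). Identical representatives arising on different transcripts are
reported jointly. The abundance filter is strict: a candidate is present
in a library iff it has **more than** 50 raw reads there (50 is excluded,
51 included); the filter applies to raw counts, not RPM, and presence in
every library defines the core set. A candidate is cleavage-concordant
when one alignment end lies within ±1 nt of the predicted cleavage
position. The 21-nt phase register relative to the cleavage site is
computed and reported but never filtered on — out-of-phase secondary
siRNAs are a documented biological outcome, not an artifact.

## siRNA clusters

The non-miRNA pool is placed exact-full-length on repeat and EST
references, both strands; a read with k placements contributes 1/k to each
so total read weight is conserved. Placements within a 100 nt gap merge
transitively into clusters (the gap is configurable; 100 nt is typical
small-RNA cluster practice and is recorded in output metadata). Category
priority for annotation: named repeat class > TC EST > unannotated repeat
> unannotated-siRNA-cluster (reads with no placement). Per-library
category fractions are read-weight fractions over the whole pool and sum
to 1; per-category length histograms expose size shifts such as the
LTR-gypsy 24→21 nt shift under stress.

## The synthetic study

`synthetic_truth()` fixes the study conditions: 4 libraries × 10⁵ reads
(desk scale, seconds to generate, with every planted signal far above its
detection threshold), twelve conserved mature miRNAs including one 22-nt
trigger and one star sequence, a planted 1-mismatch isoform, a 2-fold
miR159 induction and 2-fold miR164 repression at 24 h, ~8 % t/rRNA
contamination, a repeat mixture (16 % LTR-gypsy, 12 % TC EST, …) with the
LTR-gypsy size shift, a ta-siRNA whose 5′ end sits 1 nt 3′ of the
trigger's cleavage site at 600–1400 reads per library, three
library-specific candidates, and background reads at 21/22/24 nt peaks
(weights 0.40/0.25/0.35) with a 0.6 probability of 5′-U. Background reads
are clean negatives by rejection: they share no 18-mer with any reference
and sit > 3 mismatches from every equal-length miRNA window. Decoy target
sites each violate a named duplex rule (mismatch at position 10; adjacent
mismatches at 5–6; a 3-run at 14–16).

What the generator does **not** emulate: sequencing error and quality
profiles, isomiR/degradation ladders, adapter dimers, genuine repeat
polymorphism, or depth imbalance between libraries. Passing the planted
recovery tests therefore demonstrates the correctness of the rule chain,
not robustness to real-data noise — on real libraries the exact-match
filters are conservative by design.

## Numerical choices and degenerate inputs

* Fisher p-values follow the convention of summing table probabilities ≤
  the observed probability (with the usual 1+1e-7 relative tolerance).
* Bonferroni m is per library pair (per-contrast correction), matching how
  pairwise tables are reported.
* The MFE ratio is clamped to [0, 1]; an all-mismatch duplex has energy
  ≥ 0 and ratio 0. A miRNA whose perfect complement has non-negative
  energy is rejected as degenerate.
* Empty inputs flow through: empty FASTA → zero reads; an empty library
  yields all-zero category fractions; no 22-nt trigger → empty candidate
  table.
* Ties everywhere break lexicographically (reference ids, representative
  sequences), making every output order-deterministic.
* Whether "filtered reads" should be counted before or after contaminant
  removal is ambiguous in the field's reporting; the filter report carries
  both (`after_complexity`, `after_contaminant`).
* Pooled libraries are treated independently (no depth matching before
  pooling); RPM normalisation absorbs depth differences.

## Problem sizes used by the test suite

Unit tests run on handcrafted fixtures; property sweeps use 2 000 random
duplexes (10⁵ in the acceptance suite), an exhaustive Fisher sweep over
all 2×2 tables with totals ≤ 12 plus 4 000 random tables with totals up to
200, and end-to-end recovery on the default 4 × 10⁵-read synthetic study.
These sizes were chosen so the full suite exercises every rule boundary
while remaining a desk-scale run.

## Known limitations

Exact-match contaminant and cluster mapping will under-filter/under-map
reads carrying sequencing errors; adapter trimming does not handle 5′
adapters or UMIs; the energy model is a scoring device for the ratio
criterion, not a folding engine; novel-miRNA discovery (hairpin folding)
and degradome validation of cleavage sites are out of scope.
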