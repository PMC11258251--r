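---
title: "Mapping a chromatin boundary at an inverted repeat with non-denaturing bisulfite footprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a chromatin boundary at an inverted repeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irboundary)
```

## The assay and the model

Sodium bisulfite deaminates cytosine to uracil (read as thymine) only on
single-stranded DNA. When chromatinized, double-stranded DNA is treated
*without* denaturation, conversion therefore reports transient
single-stranded exposure — a footprint of chromatin openness — rather than
methylation. Each strand carries its own record: conversions on the top
strand appear as C→T at reference C positions; conversions on the bottom
strand appear, in top-strand coordinates, as G→A at reference G positions.
The per-base readout is the strand-specific CT conversion rate

* top strand (%) = T / (C + T) × 100 at reference C positions,
* bottom strand (%) = A / (G + A) × 100 at reference G positions,

with non-C/T (resp. non-G/A) bases excluded from the denominator.

Inside a Ty1-like LTR retrotransposon, a ~39 nt inverted repeat (IR;
element coordinates 1011–1049 in the canonical geometry used here)
separates an exposed upstream region (conversion around 20%) from a
protected gene-body region (conversion below 5%). `irboundary` formalizes
that "tipping point" as a single changepoint in a two-regime binomial
model: at informative position $i$ with conversion count $x_i$ out of
depth $n_i$,

$$x_i \sim \mathrm{Bin}(n_i,\; p_\mathrm{up}) \text{ for } i \le k,\qquad
  x_i \sim \mathrm{Bin}(n_i,\; p_\mathrm{down}) \text{ for } i > k,$$

and the boundary estimate maximizes the profile likelihood over $k$.

## What the simulator emulates — and what it does not

`simulate_ty1_like_reference()` draws an iid background at a yeast-like GC
content (default 0.40) and plants one IR (arm 15 nt, loop 9 nt, left-arm
start 1011 by default, giving the canonical 1011–1049 span). Candidates
are rejected until the IR detector reports exactly the planted annotation,
so the planted IR is guaranteed unique and maximal.

`simulate_bisulfite_reads()` samples molecules from both strands
(`strand_fraction_top`, default 0.5), exposes each cytosine of the strand
of origin with the regime probability of its position (`p_up` = 0.20
upstream, `p_down` = 0.04 from the boundary on, by default), converts
exposed cytosines with probability `conv_eff`, and applies uniform
substitution sequencing errors afterwards (`seq_error`, default 0.002 per
base, a MiSeq-like rate). Read length defaults to 250 nt (250-cycle
MiSeq-style sequencing) and the default depth is 20,000 reads over 2 kb.
Ground truth is returned per read (origin, strand, conversion count) and
per position (exposure probability, coverage, conversions), so every
downstream stage can be checked against it.

Two exposure-correlation modes are provided because the spatial
correlation of real ssDNA exposure along a molecule is unknown:
`per_base` (independent exposure per cytosine per molecule; the default
null) and `per_molecule_segment` (one exposure draw per molecule per
constant-exposure segment, i.e. contiguous exposed patches). Both have the
same marginal per-position conversion probability; the segment mode
inflates between-molecule variance.

Deliberately not modelled: PCR duplicates, adapter contamination, quality
score structure (FASTQ qualities are constant), indel sequencing errors
(reads with indels are a *filtered* class in the published pipeline, so a
separate injector flag, `indel_read_fraction`, plants them to exercise the
filter), and any sequence repeat structure beyond the planted IR. Passing
tests on these simulations therefore validate the estimators'
correctness, not robustness to library artefacts that real data may
contain.

## The bisulfite aligner

Reads are aligned under three-letter reduction: top mode collapses C→T in
both read and reference, bottom mode collapses G→A, and both orientations
of the read are scanned, so conversions are invisible to the aligner while
real mismatches are not. The implementation seeds with three k-mers per
read/orientation/mode (k = 24 by default) against collapsed-reference
k-mer tables and verifies every candidate placement by a full ungapped
mismatch count; the fewest-mismatch placement wins, with a default
mismatch budget of 10% of the read length after collapse (a permissive
analog of the local-alignment score floor used with 250 nt bisulfite
reads). An optional gapped mode re-aligns reads that fail the ungapped
budget and records indel edit operations.

Two filters reproduce the published read cleanup:

* **Ambiguity** (the MAPQ ≤ 1 multi-mapper analog): a tie for the best
  score at more than one (locus, orientation) flags the alignment, and
  `filter_alignments()` drops it.
* **Indels**: any alignment whose CIGAR contains I or D operations is
  dropped.

A read with no conversions matches both collapse modes at its true locus
with identical scores. These mode ties are *not* ambiguity: discarding
such reads would inflate low-exposure conversion estimates (zero-conversion
reads are enriched exactly where exposure is low), and assigning them all
to one strand would deflate that strand's denominator symmetry. They are
therefore assigned by a deterministic parity hash of the read id —
unbiased between strands, yet byte-reproducible. The same reasoning means
a handful of reads carrying a single conversion can be tied or out-scored
when a sequencing error happens to be invisible under one collapse but not
the other; these rare events swap strand labels but do not bias pooled
rates.

Base counts are kept in top-strand coordinates partitioned by mapped
strand, so top-strand T counts are never contaminated by bottom-strand
reads; the bottom-strand formula then reads conversions as A at reference
G positions, exactly as printed above. Rates are reported as NA below
`min_depth` informative bases (default 10; no published threshold exists,
and 10 keeps single-molecule noise out of the profile at the depths used
here).

## Boundary estimation and inference

`detect_boundary()` performs an exhaustive scan over all candidate
changepoints (cumulative sums make the whole scan O(n); profiles are ~2 kb,
so exactness costs nothing and the scan doubles as its own reference
implementation). By default strands are pooled — in this assay each
position is informative on exactly one strand (C positions top, G
positions bottom) — with a per-strand option since both strands are
expected to show the same transition. NA positions are skipped, never
imputed. Candidates need `min_side` (default 10) informative positions on
each side. When several candidates sit within one log-likelihood unit of
the optimum the leftmost is reported and a plateau flag is set.

Two p-values are reported against the one-regime null:

* a χ² approximation with 2 degrees of freedom on the likelihood-ratio
  statistic. Because the statistic is *maximized over candidates*, this
  approximation is anticonservative — useful as a screening number, not
  calibrated;
* an optional permutation p-value (`n_perm` profile permutations with the
  same candidate restrictions), which is exact under exchangeability of
  positions and is the calibrated choice. The type-I error of the
  permutation test at α = 0.05 is verified by simulation in the test
  suite (500 single-regime replicates).

The reported `position` is the first profiled position of the downstream
regime; because only C/G positions are informative, it can sit a few
nucleotides downstream of the physical boundary even at high depth.

`regime_summary()` reports both the mean and the extremum of each window
(upstream max/mean, downstream min/mean) because a printed statement like
"conversion reached 20%" does not disambiguate a plateau mean from a
maximum; both are computed over non-NA positions only and an empty window
is an error.

## Inverted repeats, hairpins and MBN-PCR

`find_inverted_repeats()` reports *maximal* IRs: annotations whose arms
pair (reverse-complement match, N never pairs) with at most
`max_mismatch` internal mismatches, whose outermost and innermost pairs
match, and which cannot be extended by one further complementary pair
either outward (same loop) or inward (loop shrunk by two, still at least
`min_loop` = 3). Detection expands arms from every candidate loop
placement; the test suite checks it against a literal enumeration of all
(arm, loop) placements on sequences up to 300 nt, and against the mirror
symmetry under reverse complement.

`fold_hairpin()` is a Nussinov-style base-pair maximization (nested pairs,
minimum loop 3, Watson–Crick only by default, G·T wobble optional). A
thermodynamic folder is unnecessary here because the readout used is
qualitative — the wild-type IR folds, the stem mutant does not — and pair
maximization preserves exactly that ordering. One consequence worth
knowing: arbitrary sequence retains substantial background pairing under
pure maximization (the left arm plus loop alone typically keeps ~40% of
the wild-type score), so `apply_ir_mutation(kind = "stem_mt")` targets a
folding score below 0.75 of wild type (default `fold_fraction`), which for
the canonical geometry also places the mutant below the MBN cleavage
threshold. The substitution itself is deterministic: the right arm is
replaced by the reversed (non-complemented) left arm, which abolishes all
arm pairing while preserving base composition, followed by a greedy
per-base repair sweep if background pairing still exceeds the target.

Loop mutants apply the canonical point substitutions at offsets +14, +16,
+18 from the IR start (element coordinates 1025/1027/1029 for an IR at
1011). With the arm-15/loop-9 geometry, +16 and +18 fall in the loop while
+14 is the innermost left-arm base, so the single-substitution mutant
(`loop_1C`) leaves arm pairing untouched whereas the triple mutant
(`loop_3C`) clips the maximal arm by one — the documented behaviour of
both builders.

`mbn_pcr_predict()` models mung-bean nuclease digestion with a single
threshold: a PCR product is lost when any detected IR inside the amplicon
folds with at least `fold_threshold` (default 12) paired bases, i.e. the
extruded single-stranded loop of a stable hairpin is cleaved. A
thermodynamic cleavage model would add parameters without changing the
binary gel readout being reproduced. PCR binding is exact-match only
(15–35 nt primers, forward on the top strand, reverse-complement of the
reverse primer downstream); multiple alternative products raise an
ambiguity error rather than guessing.

## qPCR arithmetic

`percent_recovery()` implements the percent-of-input formula literally:

$$\%\,\mathrm{recovery} = 2^{\,Cq_\mathrm{input} - \log_2(d) - Cq_\mathrm{IP}} \times 100,$$

with $d$ the dilution ratio of the input sample in (0, 1]. Note that with
$d < 1$ the $-\log_2(d)$ term *raises* recovery, which is the opposite
direction from the common convention that corrects the input Cq toward the
undiluted template; the source formula is nevertheless reproduced exactly
as printed (its companion Cq-ratio normalization note is internally
inconsistent with the exponential form and is ignored). Round-trip
identities — simulated noiseless Cqs inverting to the programmed IP
fraction — are therefore exercised at $d = 1$, where every convention
coincides, alongside the frozen worked arithmetic (Cq input 25, $d$ =
0.125, Cq IP 28 → 100%).

`simulate_qpcr()` uses $Cq = \mathrm{intercept} - \log_\mathrm{eff}(q)$
(intercept 25, efficiency 2 by default), `actual_recovery()` subtracts the
no-antibody background (negative results are allowed and flagged), and
`relative_mrna()` is a ΔCq calculator normalized to ACT1 within condition
(not ΔΔCq, as no second normalizer exists in this design). Group contrasts
use the unpaired Student t-test by default (Welch by option, one- or
two-tailed), with an error on doubly degenerate variance.

## Numerical choices and problem sizes

* Coordinates are 1-based inclusive everywhere a user sees them.
* The pipeline seed fans out as `seed + stage index` (reference, reads,
  permutation null), all well below 2³¹.
* The end-to-end test and the acceptance script run the full study
  conditions (2 kb, 20,000 × 250 nt reads), which completes in well under
  a minute on one core; unit tests use smaller references (180–1200 nt)
  and read sets (200–3000) chosen so every binomial check retains at
  least ~200× depth where a rate is being estimated.
* Oracle-equivalence suites cap inputs where the oracles are exact but
  slow: brute-force IR enumeration at ≤ 300 nt, exhaustive nested-pairing
  enumeration at ≤ 12 nt, exhaustive offset scans at a 200 nt reference.

## Known limitations

* The aligner is a specialist for short references (amplicon-scale
  footprinting); it has no FM-index and is not meant for genome-scale
  mapping, quality-aware scoring, or methylation-context calls.
* Pair-maximization folding scores are not free energies; only orderings
  and thresholded comparisons are meaningful.
* The changepoint model assumes one boundary in the searched window;
  multiple-changepoint segmentation is out of scope.
* The permutation test assumes exchangeability of positions under the
  null; depth gradients along the amplicon would violate it.
* Simulated data are iid outside the planted structure: conclusions about
  robustness to repeats, duplicated elements, or correlated exposure rest
  only on the `per_molecule_segment` variant.
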