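---
title: "Methods: SINE insertion ascertainment, genotyping and landscape analysis"
author: "sineScout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SINE insertion ascertainment, genotyping and landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short interspersed elements (SINEs) integrate by target-primed reverse
transcription (TPRT): the L1 endonuclease nicks the bottom strand at an
AT-rich site (canonically 5'-TTTT/AA-3'), reverse transcription primes from
the nick, and repair leaves a new copy flanked by a short direct repeat —
the target-site duplication (TSD) — with a 3' poly-A tail. Because a
precise excision mechanism does not exist for these elements, the *absence*
of a copy at an orthologous locus is the ancestral state, and shared
insertions are nearly homoplasy-free characters for phylogenetics. A
~100 bp platyrrhine-specific SINE family (Platy-1) is the motivating case:
its copies are ascertained from RepeatMasker annotation of one genome,
flanked, and searched in other genomes, where a present locus aligns
through the element and an absent locus shows a gap of roughly the element
length (~85-130 bp including tail and one TSD copy) between intact flanks.

sineScout re-implements this workflow as a tested pipeline: annotation I/O,
a full-length filter, flanked locus extraction, cross-genome genotyping by
seeded local alignment with gap detection, a specificity taxonomy over the
resulting presence/absence matrix, repeat-landscape statistics, TPRT
hallmark detection, subfamily discovery from lineage-specific copies, and
neighbor-joining trees with bootstrap. Because the real inputs are
multi-gigabase assemblies, every stage is validated instead on a clade
simulator whose ground truth is known exactly.

# Coordinate model and annotation I/O

All internal intervals are 1-based inclusive, the RepeatMasker `.out`
convention; conversion to 0-based half-open coordinates happens only at the
BED boundary, and the reverse-strand symbol `C` is preserved verbatim so
that files round-trip byte-exactly. For reverse-strand rows the consensus
columns appear as `(left) end begin` and are normalized on input so
`cons_begin <= cons_end` always refers to consensus coordinates. The
fragment-run id (the last column) groups pieces of one interrupted element
and is the primary evidence for nested-insertion detection.

# The clade simulator

`simulateClade()` draws a uniform-random ancestral genome, pre-seeds it
with background Alu-like and 5'-truncated L1-like copies (synthetic
consensi generated in code; see below) to a configurable coverage
(default 15%, aged by a fixed substitution dose of 0.15 so background
copies populate the older divergence bins), then walks the species tree.
Along each branch of length *t*:

* the genome accumulates Jukes-Cantor substitutions: each site is hit with
  probability $\tfrac34\bigl(1 - e^{-\frac43\mu t}\bigr)$ and replaced by a
  uniformly random different base — composing branches therefore
  reproduces the JC transition matrix for the summed dose, and realized
  element divergence is testable against the closed form;
* Poisson($\lambda t$) insertions are planted, each with a fresh TSD
  (duplication of the target bases, length uniform on 6-20 bp), a
  geometric A-tail (mean 15 bp, with a 3% chance of a heavy extension,
  mean 50 bp, to emulate rare very long tails), and an element copied from
  its subfamily consensus and aged for the remainder of the branch;
* insertion sites prefer a TT motif 5' of the site with probability 0.8
  (the endonuclease's AT-rich preference), always keep a T immediately 5'
  of the duplication (the nick base — this also keeps the duplication
  boundary unambiguous, since the right TSD copy always follows the poly-A
  tail), avoid a margin at contig ends (min(600 bp, L/10); real
  assemblies rarely carry callable insertions hard against a contig
  edge), and with probability `nestedFraction` (default 0.12, the middle
  of the ~9-14% intra-repeat integration range reported for this kind of
  data) target the interior of a background Alu/L1 copy instead, splitting
  the host into two fragments that share a run id;
* a configurable fraction (default 0.1) of insertions is planted
  5'-truncated (consensus start offset 6-59) as decoys for the full-length
  filter.

Insertions on the stem branch above the root are carried by every species
(fixed present); insertions on a tip branch by one (lineage specific). The
truth object records, per insertion, the branch of origin, subfamily, TSD,
A-tail length, nesting host and per-carrier coordinates, plus a
presence/absence truth matrix over full-length loci. An optional injector
plants identical-position insertions in a non-clade species pair to
exercise the tree-incompatibility (incomplete lineage sorting) flag; it is
off by default, so default simulations are homoplasy-free.

Default study conditions (the values the acceptance checks run under): a
five-species tree with root-to-tip depth 1.0 time unit, stem length 0.6,
genome length 5 Mb, $\lambda = 25$ insertions per unit branch length
(about 95 insertions, of which roughly 85 are full length — comfortably
above the 60-locus validation floor), and $\mu = 0.05$ substitutions per
site per unit time, i.e. ~5% root-to-tip flank divergence and up to ~10%
between distant species. These are desk-scale stand-ins for the real
setting (thirteen platyrrhine assemblies, hundreds of loci per species);
what they validate is the machinery — coordinate lifting, gap detection,
merging, classification — not genome-scale repeat biology.

What the simulator deliberately does *not* emulate: assembly gaps and
errors, segmental duplication, CpG-accelerated substitution, indels outside
of insertions, unequal base composition, and chromosome structure. Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on real assemblies.

The bundled consensus library (`syntheticConsensusLibrary()`) is
*synthetic*: four related ~105 bp SINE consensi, one 300 bp Alu-like and
one 6 kb L1-like sequence, generated from a fixed internal seed. They are
stand-ins carrying no published consensus sequence; their 3' ends are kept
free of A-runs so a planted poly-A tail has an unambiguous boundary.

# Ascertainment

The full-length filter keeps rows whose alignment starts within 4 bp of
the consensus 5' start — read as a 0-based offset, so `cons_begin <= 5` —
and reaches consensus position 103 or beyond. The end threshold is
parameterized per subfamily (default 103) because subfamily consensi can
differ in length. Flanks of 500 bp are added on both sides, truncated at
contig ends with realized lengths recorded; loci with under 50 bp of flank
on either side are flagged `short_flank` and tend to genotype `?`
downstream rather than being dropped, mirroring separate missing-value
accounting.

# Cross-genome genotyping

Genotyping re-implements the BLAT-comparison/gap-detection idea as seeded
affine local alignment:

1. **Seeding.** Exact 14-mers sampled every 7 bp from both flanks are
   matched against the target (one combined Aho-Corasick scan per target
   contig for all loci). Low-complexity seeds (fewer than 3 distinct
   bases, or a homopolymer run of 8+) are dropped — poly-A tails would
   otherwise seed spurious clusters genome-wide — and seeds with more than
   25 genomic hits are masked as overused, after BLAT's tile masking.
   Projected locus starts are single-linkage clustered at a 500 bp gap;
   clusters with at least 2 seeds become windows padded by 600 bp. A locus
   with no forward cluster is retried reverse-complemented.
2. **Alignment.** Each window is aligned to the locus under
   match +1 / mismatch −1 / gap open −4 / gap extend −0.5 (N never
   matches). If the local alignment is truncated on one side of the
   element — a deletion larger than the affine penalty can bear — a second
   block is chained over the remainder and the implied locus-only net gap
   across the junction is recorded (block stitching, as chaining aligners
   do). Per-flank identity is measured over aligned columns; flank
   coverage over the proximal 150 bp next to the element junction *or*
   the whole flank, whichever is higher — the proximal window keeps a
   distal polymorphic neighbor from voiding the anchor. Flank positions
   inside structural (30 bp or longer) locus-only gaps are excluded from
   the coverage denominator, because at an absent site the element's own
   A-tail and TSD at the start of the right flank — or an absent
   neighboring insertion anywhere in the flank — are legitimately missing
   from the target; a denominator floor of 40 bp keeps a few
   high-identity islands from passing as an anchored flank.
3. **Calling.** Code `1` when both flanks anchor (identity ≥ 0.85,
   coverage ≥ 0.80) and ≥ 80% of the element span is aligned; `0` when
   both flanks anchor and ≥ 80% of the element span lies in locus-only
   gaps with total length inside the accepted window
   $[0.6L,\ 1.3(L + a)]$ for element length $L$, where the allowance $a$
   is the larger of 100 bp and the locus's own measured A-tail + 25 bp —
   the ~85 bp absence signature scaled to the element and its visible
   tail rather than a hard constant; `?` otherwise with a machine-readable
   reason (no hit, one-flank-only, ambiguous multi-hit — best window
   score under 1.1x the runner-up —, short flank, gap outside window, low
   identity). Ambiguity is flagged, never silently resolved; the reasons
   replace manual alignment inspection with an auditable code.

Loci ascertained independently from two species are merged when each
record's projected element interval in the other source genome overlaps
the other record's element interval (reciprocal cross-mapping; projecting
the element rather than the whole flanked footprint keeps nearby distinct
loci separate); within a
merged row presence evidence dominates (1 > 0 > ?), and the source species
of a locus is always coded 1.

# Specificity taxonomy

With N species the categories are assigned with precedence: **MV** when
`?` codes reach the threshold (default the simple majority
$\lceil (N+1)/2 \rceil$, i.e. 7 of 13 — configurable); **FP** when every
non-missing code is 1 (FP is judged on non-missing species, since a
summary row can contain both FP and MV counts); **LS** when exactly one
species carries the insertion and all other non-missing codes are 0;
otherwise **Poly**, sub-categorized by the named clade whose species set
equals the presence set after excluding missing species. An unmatched
presence set is `Other`, flagged as tree-incompatible (ILS-like) when it
is not a clade of the master tree, and deletion-involved when a
contributing call carried the "gap outside window" reason. The per-species
summary counts loci over their ascertainment species, so
FP + LS + MV + Poly equals each species' locus total and sub-category
counts sum to the Poly total.

# Repeat landscape

Proximity uses gap distance (bases strictly between intervals; overlap is
0) with an inclusive cutoff of 50 bp, computed on raw annotation rows with
self-exclusion. Genome content merges same-class overlaps before counting
and treats classes independently. Divergence histograms bin the `pct_div`
column at 1% (bp- or count-weighted), conserving total masked bp per
class. Nested detection uses the fragment-run rule first — flanking rows
sharing a run id and name with consensus coordinates continuing within
±20 bp — and interval containment as a fallback; each statistic is tested
for exact agreement against an independent brute-force oracle kept in the
test suite.

# TPRT hallmarks

The A-tail extends from the element 3' end while the trailing 10-base
window stays ≥ 90% A with no run of 3+ non-A bases, then trims trailing
non-A (long natural A-tails are imperfect; the parameters are exposed).
TSD detection compares the 5' flank suffix against the sequence after the
tail for lengths 6-25 and at most one mismatch; because a TSD that begins
with adenines is indistinguishable from tail, the right-copy anchor also
backs off up to 10 bases into the measured tail, and candidates score
length − 4 x mismatches so a marginally longer imprecise candidate cannot
displace an exact duplication. Cleavage grading compares the 6 bp motif
straddling the 5' TSD start to TTTT|AA (canonical / ≤ 1 mismatch near /
none), with reverse-strand loci flipped into element sense first. The
termination scan returns the distance to the first exact TTTT within
200 bp after the 3' TSD. The detectors' false-positive behavior is
estimated on shuffled-flank nulls (< 2% at defaults over 1,000 loci).

# Subfamily discovery and trees

Assignment scores each element against every library consensus with the
same affine scheme, x10 for integer reporting — only score differences and
rankings are meaningful, never cross-tool score identity, because
RepeatMasker's scoring matrices are not reproduced here. Ties break by
lower percent divergence (p-distance over aligned non-gap columns of the
winning alignment), then library order.

Discovery follows the co-segregation idea behind COSEG as a greedy,
declared stand-in (the original's exact parameters are not reproduced):
elements are anchor-aligned onto the parent consensus, exact consensus
matches are eliminated, candidate diagnostics are (position, derived base)
pairs carried by ≥ 10 elements, the pair with the largest joint carrier
set above the independence expectation founds a subfamily and is greedily
extended while the carrier set stays at or above the minimum; the
subfamily consensus is the column majority over members. Final membership
tolerates one back-mutated diagnostic when three or more were selected —
background divergence hits diagnostic sites too, and requiring all of them
would silently shed true members. Models are named sf0, sf1, ... by
descending size. The choice of two minimum diagnostics and ten minimum
members reflects the scale at which a few dozen lineage-specific copies
can support a subfamily call.

Trees use a consensus-anchored multiple alignment (each sequence
pairwise-aligned to the longest input, columns projected onto the anchor;
insertions relative to the anchor are dropped) — adequate for ~100 bp
SINEs with a known parent, and deliberately not a progressive aligner.
Distances are p-distances over shared non-gap columns; the tree is classic
Saitou-Nei neighbor joining (via `ape::nj`, with negative branch lengths
clamped to zero); bootstrap resamples alignment columns and reports the
percentage of replicates containing each internal bipartition,
deterministic given the seed.

# Pipeline and determinism

`runPipeline()` executes simulate → ascertain → genotype → classify →
landscape → features → subfamily → tree, writing per-stage outputs, a
manifest with the seed, per-stage counts (the audit trail a summary table
would carry) and md5 checksums. Stage toggles are honored; a stage whose
inputs were not produced aborts naming the missing stage. All randomness
derives from the config seed, so identical configs reproduce byte-identical
outputs — a tested property.

# Numerical and design notes

* The validation suite runs the moderate-divergence genotyping check at
  the full 5 Mb per genome and the zero-divergence exactness check at
  2 Mb: the number of planted loci depends on the insertion rate and tree
  length, not genome size, so exactness is insensitive to the smaller
  genomes while the run stays brief.
* Degenerate inputs: empty annotation tables, empty locus sets and empty
  matrices flow through as empty results; malformed annotation rows error
  with their line number; an unparsable tree or a configuration whose
  expected output exceeds the size cap aborts before simulation.
* The `.out` dialect here is headerless-or-3-line-banner, whitespace
  delimited; `.align` files and compressed streams are out of scope.
* Known limitations: genotyping assumes diploid-free, haploid-like
  assemblies (no heterozygous sites); merging requires reciprocal
  presence evidence, so a duplicate record whose cross-call is `?` stays
  unmerged; subfamily discovery assumes a known parent consensus; the
  anchor alignment does not model insertions shared by subsets of
  sequences.
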