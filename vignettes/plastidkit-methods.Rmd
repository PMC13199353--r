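---
title: "Methods: batch comparative plastome analysis with plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch comparative plastome analysis with plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidkit)
```

This vignette documents the models and procedures behind `plastidkit`, the
parameters that matter and why they default as they do, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The setting

Chloroplast genomes of flowering plants are circular, ~150 kb, and
organized as LSC + IRb + SSC + IRa, where IRa is the reverse complement of
IRb.  A comparative study of a genus assembles and annotates many such
genomes and then asks a standard set of questions: are the IR boundaries
stable, which regions are diverse, which codons are preferred, where are
the microsatellites, and do any sites separate predefined sample groups
(for example, two sexual systems)?  `plastidkit` implements that battery as
composable functions over a simple `plastome` container (sequence +
features, 1-based inclusive coordinates, origin-spanning features stored as
split intervals with a flag).

## Orientation and start normalization

Assemblers emit circular genomes in arbitrary orientation and rotation.
`orient_to_reference()` counts exact 21-mers shared with the reference for
the input and its reverse complement and keeps whichever shares more; if
neither shares at least 5% of anchors the sequence is deemed unrelated and
an error is raised.  `rotate_to_reference_start()` finds the reference's
first 500 bp in the circular input by a k-mer offset vote, verifies the
winning offset by direct comparison (identity ≥ 0.8 required; ties go to
the smallest offset), and applies a pure circular permutation.

*Why these numbers.*  Congeneric plastomes are typically ≥ 98% identical,
so exact 21-mers are abundant on the correct strand and essentially absent
on the wrong one; 500 bp is long enough to be unique in a 150 kb genome and
short enough that a 20% mismatch budget tolerates real divergence.  Both
are exposed as arguments; neither is sensitive in practice.

## IR detection

`detect_inverted_repeats()` replaces external self-alignment with an
internal maximal reverse-complement repeat search:

1. the genome is doubled (so a rotation placing the origin inside an IR
   changes nothing; reported coordinates are taken mod L);
2. 31-mers sampled every 7 bp are looked up in the reverse complement;
   matches falling on a common antidiagonal are chained, tolerating gaps up
   to 300 bp (a substitution breaks the exact k-mer run but not the chain);
3. chains are extended base-by-base while the reverse-complement pairing is
   exact, scored by per-base identity, and kept if the copy length lies in
   **18,000–32,000 bp** (the canonical angiosperm IR window) at identity
   ≥ 99.5%;
4. the longest qualifying pair wins; two distinct non-overlapping pairs of
   equal maximal length raise an ambiguity error rather than guessing.

The copy whose downstream single-copy neighbour is shorter is IRb, giving
the forward order LSC–IRb–SSC–IRa.  A junction is reported as the
coordinate of the last base of the upstream region (so JLB is the last LSC
base).  Junction-gene reports measure distance from the feature end nearest
the junction (0 when abutting) and consider only features wholly inside the
flanking region for the left/right slots; a feature containing the boundary
is reported as spanning, with its overhang into each side.

Because extension is exact, boundaries are recovered base-exactly whenever
the IR ends are not themselves mutated; substitutions strictly inside a
copy only lower the identity.  The identity floor substitutes for an
aligner's E-value and is configurable; equivalence of coordinates, not
byte-compatibility with any particular external tool, is the contract.

## Codon usage

CDS features are spliced in translation order (minus-strand parts reverse
complemented); IR-duplicated genes contribute both copies, matching
whole-genome codon totals.  Counting reads non-overlapping triplets from
position 1: a trailing remainder is dropped with a warning, the terminal
stop codon is excluded, and triplets containing N are skipped and tallied.
Genes with an internal in-frame stop are retained in extraction but
excluded from the counts that feed RSCU (and listed in `skipped`), because
pseudogene stops would otherwise distort the stop and sense families; the
`drop_internal_stop` argument restores inclusive counting.  RSCU uses the
plastid/bacterial code (NCBI table 11); an unobserved family is undefined
(`NA`), not zero, and within every observed family the values sum to the
family size — an identity the tests assert to 1e-9.

## Repeats

**SSRs.**  A maximal perfect run of a 1–6 bp motif is reported when its
full copy number meets the per-motif-length minima **10 / 5 / 4 / 3 / 3 /
3** (mono → hexa), the settings plastome studies conventionally use.  Runs
whose motif is a power of a shorter motif (e.g. `ATAT`) are reported once,
at the fundamental period; motifs are reported in forward-strand leftmost
phase, without reverse-complement merging.  Compound (interrupted) SSR
merging is not implemented.  The scan is regex-based; the test suite proves
it equal to a position-by-position brute-force oracle on random and planted
sequences.

**Tandem arrays.**  Alignment-scored detectors admit imperfect copies;
`plastidkit` deliberately detects *perfect* maximal arrays (period ≤ 500,
total array length ≥ 25 bp, fractional final copies allowed), with the
containment rule that an array reported at a smaller period suppresses its
re-readings at larger periods.  25 bp is the perfect-array length at which
a match-weight-2, min-score-50 scoring scheme would first report.  Counts
from alignment-scored tools are therefore not directly comparable, and the
package makes no claim that they are.

**Dispersed repeats.**  Maximal exact repeated pairs ≥ 30 bp, classified
forward (same strand) or palindromic (strand vs reverse complement), with
non-overlapping copies; when a partition is supplied, pairs lying ≥ 90%
within the two IRs — the IR self-match — are excluded.  30 bp exact is a
deliberate, configurable floor in the absence of a canonical setting.

## Standardized regions and diversity

To compare intergenic spacers across samples, gene units are renamed by
four rules, applied in order: (1) annotated names are kept; (2) a gene
present as several *distinct* fragments (the trans-spliced `rps12`) has its
fragments numbered `_part1`, `_part2`, … in genomic order; (3) a name
recurring with identical content (an IR duplicate) becomes `_copy1`,
`_copy2`, …; (4) units that overlap or are separated by fewer than 10 bp
merge into `A-merge-B`.  Fragments are distinguished from duplicates by
spliced length: equal length ⇒ copies of one fragment, unequal ⇒ different
fragments.  The annotation itself does not say which is which, so this is
the package's convention; it reproduces the conventional worked names
(`rps12_part1`, `rps12_part2_copy1`, `trnH-UGU-merge-matK`).  Merging is
applied along the linear forward strand; the circular last-to-first gap is
still emitted as an IGS, but units are not merged across the origin.

Units (CDS, tRNA, rRNA, merged) then tile the genome: every inter-unit gap
becomes an IGS named `leftGene-rightGene` in forward order, including the
circular gap, and the tiling is exact — unit spans plus IGS lengths sum to
the genome length, a property the tests assert.  CDS regions carry the
spliced coding sequence; IGS regions the genomic gap.

Groups are keyed by the reference sample's region names (default: the
lexicographically first sample, approximating "the first genome in the
dataset"); regions absent from the reference go to a structural-variation
table rather than being silently dropped, and reference regions missing in
a sample simply lower that group's n.  Grouping is by name, so it is
reference-dependent by construction — choosing a different reference
changes the group keys, which is documented behaviour rather than a defect.

Alignment of a group uses `mafft` when an executable is configured or found
(the default), and otherwise a deterministic built-in star alignment:
every sequence is globally aligned to the longest one with affine gaps
(match +1, mismatch −1, gap open 5, gap extend 1 — values that keep a
single indel as one block at the ≥ 95% identity typical of congeneric
regions) and the pairwise gap patterns are merged.  Gap placement at exact
score ties follows the alignment engine's deterministic traceback.  Either
way, ungapping any output row reproduces the input exactly — asserted for
every path.

Diversity per aligned region follows the Nei–Li definition: the average
number of nucleotide differences per site over all pairwise comparisons,

$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L_{ij}},$$

where a column contributes to pair (i, j) only if both rows carry an
unambiguous base (pairwise deletion; N is treated like a gap).  Complete
deletion is available as an option; the two agree exactly on gap-free
alignments.  The SNP count is the number of columns with at least two
distinct bases, irrespective of frequency — so a region fixed differently
in two lineages can have few SNPs but substantial π, and the two statistics
are intentionally reported side by side.  Length polymorphism flags samples
whose raw region length deviates from the group median by ≥ 50 bp
(configurable), the pattern of a rare large insertion in an otherwise tiny
spacer.  The diagnostic-site screen returns every column at which two
predefined groups are each monomorphic for different bases; positions are
alignment columns by default, with an optional mapping to ungapped
positions in a chosen reference row, since "site k" in the literature can
follow either convention.

## Phylogenomic export

`build_supermatrix()` concatenates per-gene alignments in the order given
(reference genomic order in the pipeline), gap-filling samples that lack a
gene, and emits 1-based partition coordinates (`DNA, gene = start-end`
lines for ML tools).  Of IR-duplicated CDS, one copy (the IRb copy) enters
the matrix by default — both copies are near-identical, and including both
would double-weight those genes.  `annotate_tree_tips()` suffixes tip
labels with `|trait` by editing the newick text in place, so topology and
branch lengths are preserved byte-for-byte.

## The synthetic generator

`make_plastome()` builds LSC + IRb + SSC + revcomp(IRb) at ~36% background
GC (plastome-like; LSC composition in real genomes is ≈ 35–36%), with a
gene layout exercising every structural case the pipeline must handle:
IR-duplicated genes, a three-fragment trans-spliced gene, an
intron-containing gene, a nested pair triggering the merge rule, a gene
spanning the SSC/IRa junction with known overhangs (4,500/1,000 bp), and a
2 bp spacer between two SSC genes.  Defaults are 80 kb / 25 kb / 17 kb
(147 kb total), inside the observed angiosperm ranges.  Flanking bases at
the IR ends are adjusted so the planted repeat is exactly maximal —
otherwise a chance complementary base would extend the true boundary and
"exact recovery" would be ill-posed.  Planted SSRs, a tandem array and
dispersed pairs are likewise flank-broken.  CDS sequences are ATG + random
sense codons + TAA, so internal stops never occur by construction.

`make_population()` derives n samples: independent substitutions at a
per-site rate (default 0.002, a plausible congeneric divergence),
`n_diagnostic` third-codon-position sites in `rps15` fixed alternately
between two half-populations (alleles chosen never to create a stop), and
by default one 106 bp insertion in the 2 bp spacer of the last sample,
emulating a rare species-specific length expansion; random substitutions
colliding with diagnostic sites are resampled.  Annotations are lifted over
insertions, and the manifest records every edit, so "apply the manifest to
the base gene" is a testable oracle for extraction.

All randomness passes through R's seeded integer sampler; no floating-point
enters sequence synthesis, so a seed reproduces the dataset byte-exactly.

What the generator does *not* emulate: rate heterogeneity among sites or
lineages, recombination, inversions, gene loss, annotation errors, and
sequencing artefacts.  Passing tests on this data therefore demonstrate
algorithmic correctness — exact boundary recovery, oracle equality,
invariant preservation — not robustness to messy real annotations, which
varies with upstream annotation quality.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere a user sees them; circular
  intervals may have start > end (wrapping the origin).
* Ambiguity codes other than N are converted to N with a warning; N is
  excluded from GC denominators, codon counts and diversity states.
* π over pairs sharing zero valid columns: such pairs are skipped while
  the divisor stays n(n−1)/2 (they contribute 0), a case that arises only
  in pathological alignments.
* Alignment groups drop empty sequences with a warning; fewer than two
  non-empty sequences is an error, and a group of identical sequences is
  returned as its own (gap-free) alignment without invoking an aligner.
* IR detection refuses genomes shorter than twice the minimum copy length
  and reports ambiguity rather than picking between equal-length candidate
  pairs.

## Problem sizes used in the tests

The shipped tests and the acceptance script run on generator defaults:
147 kb genomes (20 seeds for boundary recovery), six-sample populations
(20 seeds for diagnostic-site recovery), 100 random alignments up to
30 × 2,000 for the π oracle, and 50 composite ~10 kb sequences for the SSR
oracle — sizes at which every oracle comparison is exhaustive while a full
run stays in the minutes range on one core.

## Known limitations

* Perfect-repeat approximations: imperfect tandem arrays and degenerate
  dispersed repeats are invisible by design.
* Region grouping is name-based; a mis-annotated gene name in one sample
  sends its flanking spacers to the structural-variation table rather than
  into the group, which is conservative but loses those samples for that
  region.
* The merge rule applies linearly; a gene pair closer than the threshold
  *across the origin* would not merge.
* The built-in star aligner is adequate for closely related sequences; for
  divergent groups an external aligner should be configured.
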