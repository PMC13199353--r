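# plastidkit

Batch comparative analysis of annotated chloroplast genomes (plastomes) in
R: structure, repeats, codon usage, region-based nucleotide diversity, and
phylogenomic export.

Angiosperm plastomes are circular molecules of roughly 150 kb with a
conserved quadripartite architecture — a large single-copy region (LSC), a
small single-copy region (SSC), and two identical inverted repeats (IRb,
IRa) — and comparative studies of a genus routinely process dozens of
annotated GenBank records at once. `plastidkit` is aimed at that setting:
it takes a directory of annotated plastomes (plus, optionally, unoriented
FASTA assemblies and a reference), normalizes orientation and start
position, detects the IR boundaries, and computes the standard comparative
battery reproducibly, with no external web tools.

## What it computes

* **Orientation and rotation** against a reference, by exact k-mer anchor
  sharing (k = 21) for strand choice and a leading-anchor vote (500 bp)
  for the start position.
* **IR detection and the quadripartite partition.**  An internal maximal
  reverse-complement repeat search (seeded k-mer chains, exact end
  extension, identity floor 99.5%) finds the IR pair with copy length
  constrained to 18,000–32,000 bp, labels LSC/IRb/SSC/IRa, reports the
  four junctions JLB/JSB/JSA/JLA, and lists genes spanning or adjacent to
  each junction with distances in bp.
* **Genome statistics**: lengths, per-region GC content, gene counts, and
  the coding fraction (union of CDS intervals).
* **Codon usage.**  Codon counts over all protein-coding genes (terminal
  stop excluded, both IR copies counted) and relative synonymous codon
  usage under the plastid/bacterial genetic code (translation table 11):
  for codon *i* in a synonymous family *F*,
  RSCU_i = |F| · x_i / Σ_{j∈F} x_j.
* **Repeats**: microsatellites (SSRs) with the standard minimum-copy
  thresholds 10/5/4/3/3/3 for mono- through hexanucleotide motifs; maximal
  perfect tandem arrays (period ≤ 500, array ≥ 25 bp); and dispersed
  forward/palindromic exact repeats ≥ 30 bp with the IRb/IRa self-match
  excluded.
* **Region-based diversity.**  Each genome is partitioned into
  standardized CDS and intergenic-spacer (IGS) regions (fragment,
  duplicate-copy and merged-unit naming rules: `rps12_part1`,
  `ycf2_copy1`, `trnH-UGU-merge-matK`, …), regions are grouped across
  samples via a reference, aligned (mafft when available, a deterministic
  built-in star aligner otherwise), and scored with the Nei–Li nucleotide
  diversity

      Pi = 2 / (n(n−1)) · Σ_{i<j} d_ij / L_ij

  (pairwise deletion), SNP counts (variable alignment columns), raw-length
  polymorphism, and a two-group diagnostic-site screen (columns at which
  two predefined sample groups are each fixed for different bases).
  Regions absent from the reference are written to a structural-variation
  table.
* **Phylogenomic export**: a concatenated CDS supermatrix with a
  RAxML-style partition file, and trait annotation of newick tree tips.
* **Synthetic data.**  A seeded generator builds plastomes with planted
  IRs, genes (including trans-spliced, IR-duplicated, nested and
  junction-spanning cases), SSRs, tandem and dispersed repeats, plus
  populations with substitutions, group-fixed diagnostic sites and rare
  insertions — every detector is testable against a ground-truth manifest.

## Worked example

```r
library(plastidkit)
res <- make_plastome(seed = 1)     # synthetic 147 kb plastome + manifest
p <- res$plastome
p
#> <plastome> synth01: 147,000 bp, 52 features (18 CDS, 5 tRNA, 2 rRNA)

ir <- detect_inverted_repeats(p)
ir
#> <ir_partition> 147000 bp
#>   LSC        1..80000   (80,000 bp)
#>   IRB    80001..105000  (25,000 bp)
#>   SSC   105001..122000  (17,000 bp)
#>   IRA   122001..147000  (25,000 bp)
#>   junctions: JLB=80000 JSB=105000 JSA=122000 JLA=147000

genome_stats(p, ir)[, c("total_len", "ir_len", "gc_total", "coding_fraction")]
#>   total_len ir_len gc_total coding_fraction
#> 1    147000  25000 40.40952        26.88571

head(find_ssrs(p, ir = ir), 3)
#>   motif motif_len copies start   end region
#> 1  TATT         4      3 16115 16126    LSC
#> 2     A         1     12 50000 50011    LSC
#> 3    AT         2      6 50500 50511    LSC

cc <- count_codons(extract_cds_sequences(p), sample_id = p$sample_id)
cc
#> <codon_counts> synth01: 13156 codons over 18 genes (0 skipped triplet(s), 0 gene(s) flagged)
head(subset(rscu(cc), amino_acid == "A"))
#>    codon amino_acid family_size count      rscu
#> 37   GCA          A           4   210 1.0023866
#> 38   GCC          A           4   211 1.0071599
#> 39   GCG          A           4   202 0.9642005
#> 40   GCT          A           4   215 1.0262530
```

The detected partition equals the generator's planted coordinates exactly;
the four Ala codons sum to the family size 4, as the RSCU definition
requires.

A typical multi-sample analysis goes
`read_genbank` → `standardize_feature_names` → `extract_regions` →
`group_regions_by_reference` → `diversity_table` /
`find_diagnostic_sites` → `build_supermatrix`.  The same steps are
scriptable from a shell via `inst/scripts/plastidkit-cli.R`
(`synth`, `normalize`, `ir-scan`, `stats`, `junctions`, `rscu`, `ssr`,
`tandem`, `dispersed`, `diversity`, `supermatrix`, `annotate-tree`).

## Limitations

Assembly, read QC, annotation and tree inference are out of scope; tandem
repeats are detected as perfect arrays (an approximation to
alignment-scored detectors such as TRF); see the methods vignette
(`vignettes/plastidkit-methods.Rmd`) for the full model description,
parameter rationale and known limitations.
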