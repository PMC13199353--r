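Package: plastidkit
Title: Batch Comparative Analysis of Annotated Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for batch comparative analysis of annotated plastomes:
    reading and writing GenBank flat files and FASTA, normalizing assembly
    orientation and start position against a reference, detecting the
    inverted-repeat pair and the quadripartite LSC/IRb/SSC/IRa partition with
    junction-gene reports, computing codon counts and relative synonymous
    codon usage (RSCU), detecting microsatellites (SSRs), perfect tandem
    arrays and dispersed forward/palindromic repeats, partitioning genomes
    into standardized CDS and intergenic-spacer regions, computing per-region
    nucleotide diversity (Nei-Li pi) and SNP counts with length-polymorphism
    and group-diagnostic-site screens, and exporting concatenated CDS
    supermatrices with trait-annotated trees.  Includes a deterministic
    synthetic-plastome generator with a ground-truth manifest for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
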