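Package: pansv
Title: Pangenome-Graph Structural Variant Genotyping and Rare-Disease Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural variation (SV) through a
    reference-backboned pangenome graph. Parses rGFA graphs, detects
    backbone-anchored bubbles (polymorphic loci) and their path alleles,
    builds binary allele-by-haplotype genotype matrices with assembly
    validity filtering, partitions alleles between sub-cohorts and computes
    allele-frequency spectra, annotates alleles (insertion/deletion/complex,
    full-length mobile elements, gene/exon/OMIM compartments, novel sequence,
    SV hotspots), benchmarks graph genotypes against reference-based VCF
    callsets (breakpoint-window matching, recall/precision), performs
    family-based analyses (sibling allele sharing with SV merging,
    permutation nulls, Mendelian-violation classification), and prioritizes
    rare exonic SV candidates with a phenotype-ontology information-content
    score. A seeded synthetic-cohort generator with a full truth set makes
    every stage testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
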