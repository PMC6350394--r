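Package: beGenomics
Title: Comparative Genomic Features of Built-Environment Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes four genomic features of annotated bacterial
    chromosomes (genome size, GC content, the GC skew index GCSI, and the
    strength of translationally selected codon usage bias, S) together with
    intra-genus 16S rRNA diversity (mean pairwise K80 distance and Faith's
    phylogenetic diversity), and compares feature distributions between a
    "Common BE" (built-environment) group and all other genomes using
    Wilcoxon rank-sum tests, Benjamini-Hochberg FDR control and Cliff's
    delta effect sizes. A synthetic-data module generates GenBank-format
    chromosomes and K80-evolved alignments with known ground truth so the
    whole pipeline can be exercised and validated without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ChromosomeRecord-methods.R'
    'beGenomics-package.R'
    'codon-selection.R'
    'composition.R'
    'diversity.R'
    'genbank-io.R'
    'group-stats.R'
    'grouping.R'
    'pipeline.R'
    'simulate.R'
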