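Package: histscreen
Title: Bar-Seq Fitness Profiling and Phenotype Analytics for Histone Mutant Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled yeast histone H2A/H2B mutant screens:
    simulation of barcode-sequencing (bar-seq) amplicon experiments, paired-end
    FASTQ demultiplexing and TAG-barcode counting with full read accounting,
    exact-test depletion statistics with FDR and FWER control for calling
    stress-sensitive alleles, analytics over ordinal phenotype-severity
    matrices (stress classes, residue aggregation, set relations, conservation
    comparisons), chromosome-loss instability calling from sectored-colony
    counts, silencing-phenotype classification, and mapping of phenotype
    residues onto the nucleosome crystal structure with a permutation test for
    spatial clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
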