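Package: medflyvirome
Title: Virome Triage, Viral Small-RNA Profiling and Abundance
    Quantification for the Mediterranean Fruit Fly
Version: 0.1.0
Authors@R:
    person("Raquel", "Ferrer", email = "rferrer.bioinf@example.org",
           role = c("aut", "cre"))
Description: Tools to re-analyse the RNA virome of the Mediterranean fruit
    fly (Ceratitis capitata) and similar insect systems: a typed catalogue
    of the 13 known medfly RNA viruses, a viral-candidate triage cascade
    over transcriptome assemblies (homology e-value, length, host-genome
    and open-reading-frame filters plus a terminal-coverage check), a
    built-in exact/1-mismatch matcher of 18-32 nt small-RNA reads to viral
    genomes, per-virus viral small-RNA profiles (length-by-strand
    histograms, 5' base composition, coverage breadth), rule-based
    siRNA/piRNA/degradation signature classification, qPCR and read-count
    viral abundance quantification, and synthetic-data generators with
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
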