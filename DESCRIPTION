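Package: MetaTide
Title: Time-Series Marine Shotgun Metagenomics: Abundance, Co-Abundance
    MAGs, Pfam-Profile Classification, Repeats and Periodicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term time-series shotgun metagenomics of
    seawater. Converts read-mapping results into copies-per-liter contig
    abundances, clusters contigs into metagenome-assembled genomes (MAGs)
    by Pearson co-abundance canopy clustering, classifies MAGs
    taxonomically by correlating Pfam domain-count profiles against a
    reference genome database, aggregates BLAST tabular hits with a
    lowest-common-ancestor rule, scans reads for 2-10 bp tandem
    (microsatellite) repeats, classifies per-MAG abundance time series
    into cyclic/transient/irregular patterns by a peak-recurrence rule,
    and renders a simplified digital-DNA-chip hybridization view.
    Includes seeded synthetic-data generators with ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
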