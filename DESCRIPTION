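Package: microxia
Title: Integrated Proteome and Transcriptome Analysis of Microoxic
    Adaptation in Rhizobia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for count-based shotgun-proteomics analysis of
    bacteria grown under oxic versus microoxic conditions, modelled on
    the Bradyrhizobium diazoefficiens free-living microoxia system.
    Implements target-decoy FDR control on peptide-spectrum matches,
    protein inference from unambiguous (class 1a/3a) peptide evidence,
    negative-binomial differential abundance on spectral counts,
    best-hit cross-strain ortholog mapping with deletion-block
    detection, consensus membrane-topology classification, integration
    of transcriptome and proteome expression calls including a
    transcript-up/protein-flat discordance classifier for
    post-transcriptional-control candidates, COG category enrichment,
    and a fully synthetic data generator with known ground truth that
    exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
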