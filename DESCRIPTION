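Package: zgakit
Title: Promoter Classification and Quantitative Chromatin Analysis at
    Zygotic Genome Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to classify zygotically activated promoters by the
    histone variant H2A.Z and to quantify the chromatin consequences of
    depleting its chaperone. Implements strand-specific nascent
    transcription peak calling with promoter-activity assignment,
    nucleosome dyad calling from fragment midpoints with replicate
    consistency rules for +1/-1 nucleosome assignment, maternal/zygotic
    transcript classification from TPM, negative-binomial differential
    occupancy with reference-set and spike-in normalization, RELACS-style
    quantitative ChIP double-ratio scaling, Hi-C matrix balancing with
    multi-depth insulation scores and boundary calling, and the
    statistical half of an IP mass-spectrometry enrichment analysis
    (filtering, shifted-normal imputation, moderated t-test,
    Benjamini-Yekutieli correction). A synthetic embryo-genomics data
    generator with planted ground truth makes every stage testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
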