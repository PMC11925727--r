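Package: rgrtools
Title: Design and Simulation of Ribozyme-Flanked Guide RNA Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing ribozyme-gRNA-ribozyme (RGR) cassettes in
    which a CRISPR guide RNA is flanked by a hammerhead (HH) and a hepatitis
    delta virus (HDV) self-cleaving ribozyme, so that functional guides are
    excised from a single RNA polymerase II transcript. Supports SpCas9
    (spacer + scaffold) and LbCas12a (direct repeat + spacer) guide
    architectures, the 6-nt HH stem rule, multiplex arrays releasing several
    guides from one transcript, in-silico simulation of ribozyme
    self-cleavage, type IIS (SapI/LguI, BbsI) Golden Gate digestion and
    ligation simulation for directional cloning into destination vectors,
    CRISPRa candidate-spacer enumeration in a window upstream of a
    transcription start site (NGG and TTTV PAMs), FASTA/GenBank input and
    output, and an illumination-dose helper for pulsed blue-light regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
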