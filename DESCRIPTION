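Package: aldhfam
Title: Genome-Wide Characterization of Plant ALDH Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for genome-wide characterization of the aldehyde
    dehydrogenase (ALDH) gene superfamily in plants. Implements family and
    subfamily nomenclature under the ALDH Gene Nomenclature Committee (AGNC)
    percent-identity thresholds via global protein alignment, PROSITE-syntax
    pattern scanning for the cysteine (PS00070) and glutamic-acid (PS00687)
    active sites, tandem versus segmental duplicate classification from
    genomic coordinates, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction and molecular dating of duplication events,
    two-species most-recent-common-ancestor gain/loss accounting,
    strand-aware promoter cis-regulatory element counting against an IUPAC
    motif catalog, expression-matrix summarization with 2^-ddCt qPCR fold
    changes, and protein molecular-weight / isoelectric-point computation.
    Seeded synthetic-data generators with ground-truth manifests support
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
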