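Package: chromarch
Title: Promoter Architecture and Chromatin Analysis of Transcription-Rate
    Changes After Topoisomerase II Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying yeast genes whose
    transcription rate changes upon topoisomerase II inactivation from
    genomic run-on (GRO) replicate tables, and for characterising the
    promoter architecture of the deregulated gene sets: promoter size and
    bidirectionality, transcription-factor binding-site bin matrices,
    GC-content and Chargaff second-parity-rule skew profiles, nucleosome
    spacing and TSS-anchored occupancy meta-profiles, dynamic
    (appearing/evicted/fragile) nucleosome overlap, chromatin-remodeler
    and histone-mark enrichment, and a curvature-symmetry score of
    nucleosome-forming potential. A synthetic-data module generates a
    complete test world (genome, annotation, GRO tables, nucleosomes,
    binding sites, tracks, gene lists) with planted, recoverable structure
    so the whole pipeline runs and is validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
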