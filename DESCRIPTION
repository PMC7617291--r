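Package: somafoot
Title: Somatic Footprints of Predisposition in Multi-Sample Tumour-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reconstructing somatic evolution from
    multi-sample tumour/normal whole-genome cohorts of one individual.
    Classifies variants as germline or somatic with a pooled-normal exact
    binomial test, separates true somatic mutations from noise with a
    per-locus beta-binomial panel-of-normals error model under
    Benjamini-Hochberg control, detects clonal expansions in histologically
    normal kidney, screens allele counts for mosaic loss of heterozygosity,
    reconstructs developmental and tumour phylogenies from shared mutations,
    annotates driver events and cancer cell fractions, and deconvolves
    mutation spectra into reference mutational signatures by expectation
    maximization. A synthetic cohort generator with full truth labels stands
    in for controlled-access patient genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
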