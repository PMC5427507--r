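Package: umbmap
Title: Consensus Genetic Linkage Maps from Low-Coverage F2 Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds framework and consensus genetic linkage maps for F2
    intercross populations genotyped by low-coverage sequencing (GBS).
    Provides parental polarization and marker quality control, sliding-window
    genotype error correction, EM estimation of pairwise recombination
    fractions under the F2 intercross model, linkage grouping and marker
    ordering, Kosambi map distances, placement of unmapped markers by minimum
    recombination fraction, consensus map merging across populations by
    order-constrained linear programming, segregation distortion scans, and
    synteny/collinearity summaries against anchored reference positions.
    Includes a synthetic F2 GBS data generator with depth-dependent
    heterozygote undercalling and viability-selection distortion, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quantreg
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
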