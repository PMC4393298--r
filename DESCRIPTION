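Package: templateseq
Title: Simulation and Template-Based Cluster Calling for
    Sequencing-by-Synthesis Tile Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates four-channel sequencing-by-synthesis flowcell tile
    images with configurable cluster density, sequence diversity, point
    spread function and noise, and re-implements the template-based cluster
    calling pipeline used by Illumina-style instruments: per-cycle spot
    detection, golden/silver cycle selection, template construction with a
    configurable template length (the Long Template Protocol), per-cycle
    image registration, intensity extraction, base calling with chastity
    (purity) filtering, and Phred-scaled quality assignment. Includes read
    quality filtering and 5' barcode matching, diverse-barcode design for
    the AasI restriction site, a binomial index-morphing null model for
    multiplexing indices, observed/expected sample-bleeding estimation on
    simulated multiplexed lanes, and the linear memory-scaling model that
    bounds feasible template lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
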