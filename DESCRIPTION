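Package: karyofish
Title: Karyotype Analytics and Oligo-FISH Signal Mapping for Metaphase Spreads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diploid plant karyotype analysis from metaphase
    fluorescence in situ hybridization (FISH) images: simulation of
    metaphase spreads with known ground truth (homolog pairs, centromeric
    constrictions, telomeric and 5S rDNA probe signals), chromosome
    segmentation and medial-axis measurement, Levan centromere
    classification and Stebbins asymmetry cytotypes, and phenetic
    clustering of species-level 5S signal profiles with Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ape,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
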