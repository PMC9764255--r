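Package: apexlfq
Title: Downstream Analysis of APEX2 Proximity-Labeling Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calling bait-proximal proteins from APEX2
    proximity-labeling experiments quantified by label-free mass
    spectrometry. Reads MaxQuant-style protein-groups tables, applies a
    presence filter followed by sequential volcano-style comparisons
    against multiple negative controls, validates the result with
    positive and negative landmark proteins, performs Fisher's exact
    category enrichment, classifies hits into integral-membrane versus
    luminal proteins, and infers membrane topology from the distribution
    of APEX2-labelable residues. A synthetic-data generator produces
    complete four-group experiments with known ground truth so every
    stage of the pipeline can be verified without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
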