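Package: acylforms
Title: Molecular-Form Enumeration and Mass Assignment for Acylated Peptide Hormones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the molecular forms of acylated peptide
    hormones such as ghrelin from MALDI-TOF mass lists. Enumerates candidate
    processed peptide species (C-terminal truncation, glycine-donor
    amidation, fatty-acyl chains of configurable length and unsaturation,
    optional adducts) from a precursor processing context, computes
    theoretical monoisotopic or average [M+H]+ masses, matches observed
    masses to candidates under an absolute mass tolerance with optional
    global calibration-offset correction, checks Edman sequencing reads for
    consistency with acyl-site modification, and simulates synthetic mass
    lists from molecular-form mixtures for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
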