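Package: glycotrim
Title: Site-Specific Glycopeptide Annotation and ER N-Glycan Processing
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-specific N-glycopeptide identification and
    glycoform quantification from deconvoluted LC-ESI-MS peak lists, and a
    deterministic rule engine for the endoplasmic-reticulum N-glycan
    processing enzymes (glucosidases I/II, UGGT, the EDEM-type mannosidases
    MNS4/MNS5, jack bean alpha-mannosidase and endomannosidase). Glycan
    structures are modelled as rooted residue trees on the canonical
    Glc3Man9GlcNAc2 topology, which lets isobaric glycoforms such as
    Man8GlcNAc2 and Glc1Man7GlcNAc2 be disambiguated from exo- and
    endo-glycosidase digestion evidence. Includes an in-silico tryptic
    digestion and sequon scanner, ppm-tolerance peak matching with
    hexose-ladder detection, relative glycoform quantification, and a
    seeded generator of synthetic deconvoluted glycopeptide spectra with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
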