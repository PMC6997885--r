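Package: memlipid
Title: Membrane Lipidome Annotation, Quantification and Biophysics for Fission Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative membrane-lipidome analysis in fission
    yeasts: shotgun lipidomics species annotation against an in-silico
    database with ppm-tolerance peak matching and internal-standard
    quantification (mol% of polar lipids); sn-1/sn-2 regiochemistry
    assignment from MS/MS neutral-loss intensities with in-silico
    phospholipase A2 digestion and acyl-asymmetry summaries; giant
    unilamellar vesicle flicker spectroscopy with Helfrich-spectrum fitting
    of the bending rigidity; natural-abundance correction of 13C
    isotopologue distributions; and comparative transmembrane-helix
    statistics across ortholog groups. Seeded synthetic-data generators
    with machine-readable ground truth make every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
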