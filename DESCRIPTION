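Package: nativemrm
Title: MS/MS-Library-Facilitated MRM Assay Design for Native Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and validating LC-MRM (multiple reaction
    monitoring) assays for native, non-tryptic peptides in body fluids.
    Provides exact monoisotopic mass and m/z arithmetic for peptides, b/y
    fragments and stable-isotope label schemes; filtering of database-search
    identifications with multi-level (spectrum, ion, peptide) target-decoy
    FDR re-estimation; construction of MS/MS spectral libraries with
    representative-spectrum selection and blib/msp input/output; enumeration
    and intensity-based ranking of candidate MRM transitions with paired
    light/heavy transition tables; and stable-isotope-dilution
    quantification (peak integration, absolute concentration, recovery,
    stability, linearity, limit of quantification, carry-over and
    cross-talk). A synthetic-data module generates identification sets,
    replicate MS/MS spectra and MRM chromatograms with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    DBI,
    RSQLite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
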