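Package: glycoGU
Title: Glucose-Unit Indexing, Annotation and Quantification of Permethylated
    Glycans from LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated processing of LC-MS glycomics runs that carry a spiked
    permethylated dextrin ladder as internal retention standard. Detects the
    ladder rungs across full-MS spectra and resolves their elution order by
    dynamic programming, fits the retention-time to glucose-unit-index (GUI)
    standard curve by polynomial or logarithmic least squares, annotates
    permethylated N-glycan compositions by matching theoretical aggregated
    isotope envelopes (computed with the BRAIN recursion) against observed
    peaks with Pearson-correlation scoring, and performs label-free
    per-isomer quantification from extracted-ion chromatograms built from the
    three most abundant isotope peaks. Includes a synthetic-run generator
    that writes standard mzML, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mzR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Proteomics, Metabolomics, Software
RoxygenNote: 7.3.3
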