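Package: diadetect
Title: Library-Free Peptide Detection in Data-Independent Acquisition
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects peptides in data-independent acquisition (DIA)
    tandem mass spectrometry runs using only a protein sequence database,
    without a spectral library. A bipartite graph is built between MS2
    spectra and candidate charged peptides via SEQUEST-style XCorr
    scoring; each candidate match is augmented with complementary
    evidence features (Tailor-calibrated XCorr, precursor isotope
    intensity rank, binomial fragment-matching P-value, retention-time
    agreement, and precursor/fragment coelution), filtered by an
    aggregate score, and re-ranked with a semi-supervised linear
    max-margin model under target/decoy-pair-constrained
    cross-validation. Peptides are reported with precursor-level
    target-decoy competition q-values. Includes a synthetic DIA run
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    mzR,
    stats,
    utils,
    xml2
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
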