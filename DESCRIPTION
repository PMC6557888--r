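Package: morphoproteo
Title: Morph-Specific Protein Profiling of Lizard Femoral-Gland Secretions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and validate colour-morph-specific protein
    profiles in lizard femoral-gland secretions from two-dimensional gel
    electrophoresis (2-DE) spot maps and tandem mass spectrometry of
    excised spots. Builds per-morph master gels from replicate spot lists
    (spots retained when present in at least two of the three best gels),
    compares master gels pairwise into high master gels (HMG) and a
    combined high master gel (CHMG) labelling morph-unique spots, performs
    a simplified peptide-spectrum-match search against a reversed-decoy
    database with a two-stage target-decoy strategy and peptide-level
    false-discovery-rate control, computes binned-cosine distances between
    per-spot spectrum sets, and tests whether within-spot (self) spectral
    distances are smaller than between-spot minimum non-self distances
    with an exact one-tailed Wilcoxon signed-rank test. A synthetic-data
    generator produces ground-truthed morph proteomes, noisy replicate
    gels and per-spot MS/MS spectrum sets for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
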