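Package: pulseN15
Title: Pulse-15N Stable-Isotope Turnover Proteomics and Ubiquitylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pulse-15N metabolic-labeling proteomics of
    long-lived proteomes. Computes peptide elemental compositions, monoisotopic
    masses, precursor and y/b fragment m/z, and theoretical isotope envelopes at
    arbitrary 15N enrichment; estimates per-peptide 14N/15N ratios from paired
    extracted ion chromatograms by regression through the origin and rolls them
    up to per-protein 15N proportions under two-peptide (total proteome) or
    one-peptide (ubiquitylome) evidence rules; classifies long-lived (LLP) and
    extremely long-lived (ELLP) proteins by threshold and fuzzy c-means
    trajectory clustering; quantifies diGly (K-GG) ubiquitylome channel
    proportions, old-protein ubiquitylation bias (Mann-Whitney), and site-count
    distributions; and builds parallel-reaction-monitoring (PRM) target tables
    with summed y3-y7 fragment quantification for ubiquitylated H2A. A seeded
    synthetic-data generator emulates the three-tissue, three-age pulse-chase
    design with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
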