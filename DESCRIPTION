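Package: hmnr
Title: Multi-Well Microelectrode Array Analysis and the Human
    Multi-Neurotransmitter Receptor Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-well microelectrode array (MEA)
    recordings of cultured neuronal networks: zero-phase band-pass filtering,
    adaptive-threshold spike detection with waveform cutouts, per-electrode
    spike sorting by EM fitting of a mixture of multivariate t-distributions,
    electrode-level burst and well-level network-burst metrics, and the human
    multi-neurotransmitter receptor (hMNR) assay in which sorted units are
    classified as neuronal subtypes by their firing-rate fold changes under
    pharmacological modulators and followed across cumulative test-compound
    concentrations.  Includes a ground-truth simulator of multi-well MEA
    recordings (spike trains, biphasic waveform templates, band-limited noise)
    with subtype-specific rate modulation, and the group-comparison statistics
    used for MEA endpoints (Brown-Forsythe variance check, one-way ANOVA with
    Dunnett contrasts, Welch ANOVA with Games-Howell pairwise tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mvtnorm,
    multcomp,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
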