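Package: helitrax
Title: Single-Molecule Analysis of Helicase Unwinding, Translocation and
    DNA Repair Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for single-molecule helicase
    experiments: synthetic kymographs, bead-distance, fluorescence-decay,
    smFRET and force-extension data with stored ground truth; sub-pixel
    kymograph particle tracking and trajectory linking; mean-squared
    displacement computation with power-law motion classification;
    Savitzky-Golay velocity and unwinding stroke-rate extraction;
    exponential dwell-time and fluorescence-loss kinetics; worm-like chain
    force-extension fitting with contour-length and loop-size estimation;
    and classification of Cas9 amplicon repair outcomes (NHEJ, MMEJ, SSTR)
    from read-versus-reference alignments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    mclust,
    jsonlite,
    tiff,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
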