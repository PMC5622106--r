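Package: fabdomains
Title: Sequence Composition, Electrostatics and Surface Burial of Antibody Fab Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the four domains of antibody Fab fragments
    (VH, CH1, VL, CL) and related immunoglobulin-superfamily (IgSF) domains.
    Curates Fab datasets from PDB-format structures by chain-length quartile
    filtering and splitting heavy and light chains at conserved interdomain
    motifs; computes sequence-based properties (amino-acid composition,
    sequence entropy, lysine-minus-arginine, isoelectric point, aromatic
    content, a charge/hydropathy folding propensity) expressed as z-score
    deviations from a reference population; estimates the contribution of
    ionisable groups to folded-state stability and dimerisation at pH 7 with
    a Debye-Hueckel continuum model and Monte Carlo protonation-state
    sampling; computes Shrake-Rupley solvent-accessible surface area and
    interface burial; and scans IgSF composition vectors for CH1-like
    domains with a differenced-cosine similarity combined with a sequence
    entropy threshold. Includes generators for synthetic Fab-like sequences,
    toy charged structures, reference populations and IgSF cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    seqinr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
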