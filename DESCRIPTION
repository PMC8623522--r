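Package: tmidr
Title: Topology-Aware Prediction of Intrinsically Disordered Regions in
    Transmembrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts intrinsically disordered regions (IDRs) in transmembrane
    proteins from sequence and per-residue membrane topology. Non-membrane
    residues are partitioned into four compartments (extracellular/cytosolic x
    membrane-distant/proximal) and each compartment is scored by its own small
    convolutional network over an 11x39 windowed feature matrix (sequence
    profile, amino-acid scales, ProtParam descriptors, topology, accessibility
    and low-complexity channels); a bidirectional recurrent smoother with a
    truncated 12-step lookback refines the per-residue scores along the chain.
    Includes the full training pipeline: consensus order/disorder labelling,
    IDR-plus-flank fragment selection, topology-aware class balancing, greedy
    40-percent-identity redundancy clustering, leakage-guarded splits,
    CAID-style residue and region-level evaluation, and a synthetic
    transmembrane-protein generator so the whole pipeline runs end-to-end
    without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
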