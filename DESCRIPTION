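Package: hfnet
Title: Hyper-Frequency Networks from Directed Cross-Frequency Phase Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed weighted hyper-frequency networks (HFNs) from
    multichannel oscillatory recordings. Instantaneous phase is extracted with a
    complex Morlet wavelet on a 20-ms grid; within- and cross-frequency n:m
    phase coupling is quantified with the phase synchronization index and a
    family of ternary-coded in-phase coupling indices (PCI, NCI, ACI, ICI) over
    sliding windows. Electrode-by-frequency networks are sparsified against
    surrogate-based significance thresholds and summarized with weighted
    directed graph metrics (strengths, clustering, path length, efficiencies)
    together with lattice and random reference graphs and small-world
    coefficients. Network topology dynamics are analyzed via temporal and nodal
    similarity matrices, signed Louvain modularity, and a feed-forward
    classifier for stimulus-related dynamics. A seeded synthetic-data module
    generates coupled-oscillator recordings with oddball-style event schedules
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
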