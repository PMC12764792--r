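Package: polyestab
Title: Spatially Explicit Agent-Based Simulation of Neopolyploid Establishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, individual-based simulator of the formation
    and demographic establishment of neopolyploid plant lineages in
    heterogeneous environments. Plants live on a lattice of patches carrying
    five environmental variables; environmental fitness follows an
    exponential-decay tolerance model around each individual's adaptive
    optimum. The simulator covers unreduced gamete production, the triploid
    bridge, selfing, apomixis, distance-weighted pollen donation, negative
    exponential seed dispersal with patch contention, and niche
    tolerance/optimum-shift scenarios. Includes experiment sweeps with
    ANOVA/Tukey compact-letter summaries, establishment statistics
    (successful and unsuccessful polyploidization events, generations to
    establishment and to tetraploid fixation), density maps of establishment
    sites, and a deterministic gametic-recursion baseline for the classical
    diploid-exclusion threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
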