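Package: cosmofret
Title: Simulation and Analysis of Single-Molecule FRET Colocalization Data
    for Helicase Loading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying eukaryotic replicative-helicase loading with
    colocalization single-molecule spectroscopy (CoSMoS) and single-molecule
    FRET. Provides a continuous-time stochastic simulator of ORC-mediated
    Mcm2-7 loading on individual DNA molecules (including the helicase-
    tethered ORC-flip mechanism, its failure branches, mutants, and
    alternative mechanistic hypotheses), a forward model that renders state
    trajectories into per-frame three-channel fluorescence traces under
    alternating donor/acceptor excitation (with FRET, protein-induced
    fluorescence enhancement, photobleaching, and noise), an optional
    synthetic TIRF image layer with spot detection and colocalization, and
    an analysis pipeline that recovers presence intervals, intensity steps,
    apparent FRET efficiency series, classified loading events, and censored
    dwell-time statistics (product-limit survival curves with Greenwood
    confidence bounds, censored-exponential maximum-likelihood fits with
    bootstrap errors, photobleaching-rate decomposition, and multinomial
    model-discrimination tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    tiff,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
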