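Package: ictalwave
Title: Conductance-Based Refractory Density Model of Ictal Discharge
    Generation and Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates seizure-like ictal discharges in a one-dimensional
    cortical domain using a conductance-based refractory density (CBRD)
    description of interacting excitatory and inhibitory neuronal
    populations.  The model couples population firing dynamics (density
    transport in time-since-spike space with a hazard-function spike
    source) to AMPA/NMDA/GABA-A synaptic kinetics with short-term
    depression, full ionic mass balances for potassium, chloride and
    sodium (Na+/K+-ATPase kinetic pump, KCC2/NKCC1 cotransporters,
    glial buffering), calcium-dependent adaptation, and dynamic
    extracellular-space volume.  Includes named in-silico experiments
    (diffusion blockade, altered connection length, all-to-all mixing,
    fixed volume, glial buffer), wavefront-speed estimators, a
    Monte-Carlo ensemble oracle for validating the density
    approximation, and synthetic fixture generators for the analysis
    layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
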