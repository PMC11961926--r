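Package: stresswm
Title: Spiking-Network Simulation of Prefrontal Working Memory Under Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis pipeline for a rodent prefrontal
    working-memory circuit built from two-compartment integrate-and-fire
    neurons coupled by AMPA, NMDA and GABA synapses with short-term
    plasticity (facilitation and depression). Four selective neuron groups
    compete through inhibition during a fixation/memory/delay/cue recall
    protocol driven by Poisson input. Stress conditions are expressed as
    model transforms: acute stress scales recurrent NMDA and AMPA currents
    by empirically derived EPSC ratios, chronic stress removes a fraction of
    excitatory dendritic spines (reducing effective synapse counts) and
    rescales GABA channel strength or within-group connection blocks. The
    measurement layer provides working-memory capacity counting, the
    spike-count autocorrelation intrinsic timescale (exponential fit by
    Levenberg-Marquardt nonlinear least squares), population mean current
    traces, and sweep correlations, plus a synthetic fixture generator for
    rasters with a known number of sustained groups and count series with a
    known autocorrelation timescale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'params.R'
    'AllClasses.R'
    'dynamics.R'
    'network.R'
    'protocol.R'
    'stress.R'
    'engine.R'
    'analysis.R'
    'fixtures.R'
    'config.R'
    'cli.R'
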