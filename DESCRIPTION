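Package: neuroenergetics
Title: Single-Neuron Energy Metabolism, Gamma-Oscillation Spectra and
    Slice-Culture Assay Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolkit for studying how extracellular
    lactate/glucose availability and energy demand shape neuronal energy
    fitness in inflamed brain tissue. Provides a reduced compartmental
    kinetic model of single-neuron energy metabolism (glycolysis, citric
    acid cycle, respiratory chain, oxidative phosphorylation,
    mitochondrial electrophysiology, NADH shuttles, MCT2 lactate
    transport and lactate dehydrogenase), steady-state phase-diagram
    sweeps over substrate availability with glucose-fitness threshold
    localization, a gamma-oscillation local-field-potential spectral
    pipeline (zero-phase Butterworth filtering, Welch power spectra,
    peak/FWHM features, oscillation classification), quantitative
    bench-data reductions (plate-assay standard curves, oxygen
    microsensor calibration and depth profiling, comparative Ct gene
    expression, heatmap z-scoring with Ward clustering), an automated
    two-channel microglia counting pipeline, and synthetic-data
    generators with known ground truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    signal,
    stats,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
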