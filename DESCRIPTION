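Package: ecptools
Title: Artifact Removal and Spike Extraction for Combined Voltammetry and
    Electrophysiology Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for concurrent electrochemical
    (fast-scan cyclic voltammetry, FSCV) and extracellular
    electrophysiological recordings. Detects periodic FSCV scan artifacts
    in multi-channel voltage recordings and removes them by temporal
    (linear) interpolation, with a variant for 60 Hz line noise and its
    harmonics. Downstream tools extract spike waveforms, compute features
    and cluster units, estimate dopamine concentration changes from cyclic
    voltammograms by principal-component projection against analyte
    standards, align spikes and dopamine traces to behavioral events, and
    quantify spike recovery after simulated artifact injection. A seeded
    synthetic-data module generates ground-truth recordings (spike trains,
    noise, scan artifacts of three morphologies, line noise, and cyclic
    voltammogram streams) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
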