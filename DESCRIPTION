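Package: respemg
Title: Respiratory Surface Electromyography Processing Toolkit
Version: 0.1.0
Authors@R: person("respemg", "developers", role = c("aut", "cre"),
    email = "maintainer@respemg.dev")
Description: Tools for processing respiratory surface electromyography
    (sEMG): cardiac-artifact removal by high-pass filtering, QRS gating and
    wavelet-domain denoising; envelope extraction by moving RMS, average
    rectified value, rectified median and fixed sample entropy; baseline
    correction; and breath-level parameter extraction including amplitude,
    normalization, EMG-time product, neuromechanical conversion to muscle
    pressure (Pmus), onset/offset timing, patient-ventilator phase angle and
    spectral fatigue indices. Includes a synthetic signal generator with
    complete ground truth, preset processing pipelines with full parameter
    provenance, EDF and CSV input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
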