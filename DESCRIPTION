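Package: astmeg
Title: Simulation and Sensor-Space Analysis of an Auditory Short-Term Memory MEG Study
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a multi-stream auditory short-term
    memory (delayed match-to-sample) MEG experiment at the sensor level.
    Includes a trial/stimulus designer for three concurrent tone-pip streams
    (3, 7 and 19 Hz), a synthetic-data generator producing multi-channel
    epochs with planted evoked, steady-state and band-limited oscillatory
    effects plus realistic 1/f, line-noise and drift backgrounds, and the full
    analysis pipeline: trial-power outlier rejection, denoising source
    separation (DSS), baseline correction, response-time-based trial equating,
    event-related field RMS bootstrap inference, cluster-based permutation
    statistics over channels and time, sliding-window Hanning time-frequency
    analysis, and neighbour-bin-normalized power spectral density analysis of
    steady-state responses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
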