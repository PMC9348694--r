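Package: numecog
Title: Numerosity Tuning Analysis for Intracranial EEG High-Frequency Broadband Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting numerosity-tuned high-frequency
    broadband (60-120 Hz) responses in intracranial EEG (ECoG and
    stereo-EEG) recordings. Builds the stimulus presentation plans of
    sequential and semi-randomized numerosity runs and visual-category
    control runs; reads and writes EDF raw recordings and BIDS-iEEG-style
    events tables; performs notch filtering, common-average re-referencing,
    epoching, evoked-signal removal, sliding-window Hanning-tapered
    time-frequency power estimation, per-frequency normalization, baseline
    correction, and high-frequency-band extraction; applies trial-level
    quality-control exclusion rules; and classifies electrodes as
    numerosity-tuned, monotonically increasing (stimulus-energy),
    flat-responsive, or nonresponsive with dummy-coded categorical GLM
    contrasts. Includes a synthetic raw-data generator with known ground
    truth (1/f background, line noise, evoked components, tuned broadband
    bursts) so that every stage is verifiable by parameter recovery without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
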