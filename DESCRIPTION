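Package: oculoscene
Title: Ocular Dynamics of Auditory Scene Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying pupil-linked arousal and microsaccade-linked
    attention during auditory scene analysis. Generates tone-cloud "scene"
    stimuli (regular vs random multi-stream soundscapes with appearing or
    disappearing streams and decoy gaps), simulates binocular 1 kHz
    eye-tracking sessions with known ground-truth effects, preprocesses pupil
    traces (blink masking, shape-preserving interpolation, Hann smoothing,
    epoching, z-normalization), extracts pupil dilation events and binocular
    microsaccades (velocity-threshold detection), converts event trains to
    causal-kernel rate series, and provides bootstrap time-point statistics
    with a surrogate-split noise floor and resampled divergence latencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
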