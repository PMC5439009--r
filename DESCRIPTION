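Package: rhythmeter
Title: Bayesian Meter Inference and Onset Prediction for Quantized Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers metrical interpretations (time-signature category and
    bar phase) of monophonic quantized rhythms by inverting a generative
    model in which a metrical category is drawn from a prior, a phase is
    drawn uniformly, and note onsets are emitted by a per-category
    variable-order (PPM*) sequence model over metrical-position symbols.
    Provides incremental posterior updating over interpretations,
    predictive onset distributions, per-event information content, a
    meter-agnostic inter-onset-interval baseline, corpus input/output
    (JSON-lines and best-effort **kern import), synthetic rhythm-culture
    generators, and simulation harnesses for cross-validated meter
    classification, prediction-error comparison, manipulated prior
    biases, and enculturation contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
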