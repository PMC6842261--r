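Package: visitCD
Title: Visit-Level Contextual Decomposition for Recurrent EHR Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains long short-term memory (LSTM) and bidirectional LSTM
    risk-prediction models on longitudinal diagnosis-code sequences and
    explains their patient-specific predictions with contextual
    decomposition (CD): an exact additive split of the network's
    pre-softmax logit into the contribution of a chosen subset of visits
    (beta) and the contribution of everything else (gamma). Includes a
    sliding-window search for the most predictive group of visits, an
    artificial-visit validation protocol, a logistic-regression
    ground-truth comparison, top-pattern mining, a synthetic
    electronic-health-record cohort generator with plantable
    visit-level signal, and a static HTML timeline visualization of
    per-visit attribution scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
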