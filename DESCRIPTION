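Package: pbrkit
Title: Probability of Being in Response for Clinical Trial Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonparametric estimation of the probability of being in
    response (PBIR/PBR), a Kaplan-Meier-style occupation probability of
    the "in response" state of a progressive three-state model
    (not in response, in response, response permanently ended).
    Implements subject-level event derivation with a response-window
    cut-off rule, the PBR estimator as the difference of two
    product-limit curves, pointwise bootstrap confidence bands,
    between-arm difference curves, expected duration of response
    (restricted area under the PBR curve), cumulative-responder curves,
    companion Kaplan-Meier endpoint summaries (response rates, time to
    first response, duration of response, failure-free survival), and a
    synthetic two-arm trial simulator with a closed-form exponential
    Markov oracle for verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    survival,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
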