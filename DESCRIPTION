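Package: gardenhunt
Title: Royle-Nichols Abundance Models and Hunting-Pattern Analysis for
    Camera-Trap Surveys in Savanna-Forest Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse camera-trap detection/non-detection data and
    hunter-interview data from savanna-forest mosaics. Builds site-by-visit
    detection histories from raw photo records, fits Royle-Nichols
    Bernoulli/Poisson latent-abundance models by maximum likelihood, ranks
    candidate models by AICc or QAICc with Akaike weights, computes
    sum-of-weights variable importance and conditional model-averaged
    coefficients, assesses fit by parametric-bootstrap Pearson chi-square
    with c-hat overdispersion correction, computes ethnozoological hunting
    importance (Hv) and preference (Pv) indexes from interviews, and tests
    hunting-site selection with logistic regression and contingency tables.
    Includes a seed-deterministic synthetic-study generator emulating a
    Gran Sabana style survey design for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
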