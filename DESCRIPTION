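Package: popdann
Title: Domain-Adaptive Neural Networks for Simulation-Trained Population Genetic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised domain adaptation in population genetic
    inference trained on coalescent simulations. Genealogies at a focal site
    are encoded as stacked lower-triangular topology/interval/derived-subtree
    matrices; gradient-reversal-layer (GRL) networks are assembled for sweep
    classification, selection-coefficient regression and recombination-rate
    regression; a built-in coalescent simulator generates matched source and
    target domains under controlled simulation mis-specification (demographic
    bottlenecks, background-selection surrogates, genealogy-inference error);
    and a four-scenario benchmarking protocol quantifies the benefit of
    domain-adaptive over standard training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
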