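Package: liemarkov
Title: Lie Markov DNA Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of the hierarchy of RY/WS/MK Lie Markov
    DNA substitution models: the twelve basis generators and the 37 model
    structures built from them, structural model properties (equilibrium base
    frequencies, nesting, time reversibility, Lie closure), the Cartesian
    parameterization of each model's stochastic cone with extreme-ray
    enumeration, Monte Carlo diagnostics for multiplicative closure and Markov
    embeddability of products of model matrices, a pruning-algorithm maximum
    likelihood engine for (non)reversible models with invariant-site and
    discrete-gamma rate heterogeneity and BIC/AICc model selection over the
    full 108-model panel, and a sequence simulator for generating alignments
    under any registered model on a rooted tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
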