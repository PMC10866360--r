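Package: investga
Title: Genetic-Algorithm Design of Inverted-Gap Organic Emitters
Version: 0.1.0
Authors@R: person("investga", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Artificial molecular-design workflow for organic emitters with
    inverted singlet-triplet gaps: a genetic algorithm over a robust
    molecular string representation with domain-knowledge pi-system
    filters, symmetry-aware azaazulene scaffold enumeration, surrogate
    neural-classifier gating of property evaluation, hierarchical
    multi-objective candidate ranking, and profactual/counterfactual
    explanation of the classifier. Chemical perception is delegated to
    RDKit via a persistent Python worker process; property oracles are
    pluggable, with deterministic synthetic and lookup oracles included so
    the complete loop runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    processx,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with rdkit on the PATH
Config/testthat/edition: 3
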