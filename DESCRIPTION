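Package: dbmcbs
Title: Deep Boltzmann Machine Model of Hallucinations in Charles Bonnet
    Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a layered (deep) Boltzmann machine model of the
    emergence of complex visual hallucinations under sensory deprivation,
    as in Charles Bonnet syndrome. Provides block Gibbs and mean-field
    inference with receptive-field-restricted connectivity, layer-wise
    contrastive-divergence training, homeostatic adaptation of neuronal
    excitability toward per-unit target firing rates, a deterministic
    top-down decoder with doubled weights, an acetylcholine-inspired
    feedforward/feedback balance factor, template-matching and
    classifier-based hallucination-quality scoring, a synthetic shapes
    corpus with input-degradation operators, and reproducible experiment
    scenarios (input corruption, blindness, noise, fixed input, half-field
    and hidden-layer lesions, suppression probes, cholinergic fluctuation,
    and contour completion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
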