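Package: tonicphasic
Title: Tonic/Phasic Dopamine Imbalance in Basal Ganglia Reinforcement
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulator of dopamine terminal dynamics (tonic and
    phasic release, Michaelis-Menten reuptake, autoreceptor feedback, D1/D2
    receptor binding) coupled to a four-channel cortico-basal-ganglia-thalamic
    action-selection network with dopamine-gated Hebbian plasticity at the
    cortico-striatal synapses.  Provides virtual-cohort experiments (training
    on a four-alternative forced-choice task, reaction-time test phase, noise
    sweeps, input-output gain curves) and the accompanying analysis battery
    (ex-Gaussian reaction-time decomposition, reward/punishment history
    statistics, group regressions), for studying how an imbalance between
    phasic and tonic dopamine release - as hypothesised in attention deficit
    hyperactivity disorder - shapes reinforcement learning and response
    variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
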