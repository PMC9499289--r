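Package: thalamoflex
Title: Thalamocortical Gating Model of Cognitive Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a thalamocortical model of cognitive flexibility in
    a probabilistic inference task. A 500-neuron rate reservoir stands for
    dorsolateral prefrontal cortex (dlPFC); a two-neuron winner-take-all layer
    stands for mediodorsal thalamus (MD) and feeds additive and multiplicative
    modulation back to the reservoir. Corticothalamic weights learn by a Hebbian
    rule with a long eligibility trace, readout weights learn by node
    perturbation against trial reward, a maximum-likelihood estimator of
    strategy value (vmPFC) supplies expected-reward inputs, and a Bayesian
    changepoint observer (OFC) routes context-switch signals to MD or dlPFC.
    Includes the blocked cue-rule task environment, lesion and gain-sweep
    experiments, routing comparisons, and post-hoc analyses (cue-responsiveness
    by logistic regression, population decoding, condition correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
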