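Package: hostarrow
Title: Discrete-Trait Evolution of Host Use on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of host association and host
    specificity in cleptoparasitic (cuckoo) bees and similar host-parasite
    systems. Implements Mk (k-state continuous-time Markov) likelihoods on
    rooted trees via the pruning algorithm, constrained maximum-likelihood
    estimation of transition rates including irreversible (one-way) models
    and a likelihood-ratio test of irreversible evolution averaged over a
    posterior tree sample, Fitch/MPR parsimony ancestral reconstruction with
    ambiguity-aware change counting, reversible-jump MCMC ancestral state
    mapping with hyperpriors, harmonic-mean marginal likelihoods and Bayes
    factor node tests, rule-based specialist/generalist classification of
    host records, host-switch enumeration, and seeded simulators for trees,
    posterior-like tree samples, Mk characters and host tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
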