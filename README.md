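# hostarrow

Discrete-trait evolution of host use on phylogenies: did host specialists
arise from generalists, generalists from specialists, or both?

`hostarrow` is an R package for studying the evolution of host association
in cleptoparasitic ("cuckoo") bees and similar host–parasite systems. Its
motivating system is the genus *Sphecodes* (Halictidae), whose species lay
eggs in the nests of other bees: some species exploit a single host genus,
others use many unrelated hosts, and the direction of evolution between
those strategies is the scientific question the package is built to answer.

## What it implements

* **Mk likelihoods and constrained ML rates.** The k-state continuous-time
  Markov (Mk) model of a discrete character evolving along a rooted tree
  with rate matrix Q, where q_ij is the rate of the i→j transition.
  Likelihoods are computed with Felsenstein's pruning algorithm; `fit_mk()`
  maximizes them under equality and zero constraints on the off-diagonal
  rates, so irreversible (one-way) models are expressed as zero-fixed cells
  and optimized on the boundary.
* **The irreversibility likelihood-ratio test.** `irreversibility_test()`
  fits three models of a binary specialist/generalist (S/G) character to
  every tree of a posterior sample — bidirectional (q_GS, q_SG free),
  G→S only (q_SG = 0) and S→G only (q_GS = 0) — averages the maximized
  log-likelihoods over the trees, and refers
  LR = 2(mean lnL_bidirectional − mean lnL_one-way) to χ² with 1 df.
* **Fitch/MPR parsimony.** `fitch_state_sets()` returns, for every node,
  the set of states attainable in at least one most-parsimonious
  reconstruction (so ambiguous nodes stay ambiguous), with
  ambiguity-aware change counting on branches.
* **Reversible-jump MCMC ancestral mapping.** `run_mcmc()` samples rates,
  an equal-versus-distinct-rates model indicator, a hyperprior mean and
  the current tree of a posterior sample; it reports mean node posterior
  probabilities, harmonic-mean marginal likelihoods, 2 ln(BF) comparisons
  (`bayes_factor_2ln()`) and fossilized-node tests
  (`fixed_state_node_test()`).
* **Host-record classification and switch counting.** The packaged
  37-species *Sphecodes* host table (`sphecodes_hosts()`) records presence
  of eight host lineages; `classify_specificity()` applies three graded
  specialist definitions (Distributions I–III), and
  `detect_host_switches()` enumerates host gains along a tree.
* **Simulators.** Seeded generators for pure-birth trees, posterior-like
  tree samples (lognormal branch jitter), exact event-by-event Mk
  character histories with recorded truth, and host tables with planted
  switches.

## Worked example

```r
library(hostarrow)

## classify the packaged host records under the main rule set
count_specificity(sphecodes_hosts(), "II")
#> specialist generalist    unknown
#>         22          8          7

## the LR stage of the irreversibility test from mean log-likelihoods
g2s <- lr_from_mean_loglik(-6.545, -8.731)
sprintf("LR = %.3f, p = %.4f", g2s$LR, g2s$p)
#> "LR = 4.372, p = 0.0365"

## end to end on simulated data: tree sample + binary character
tree   <- simulate_yule_tree(40, birth_rate = 1, seed = 7)
char   <- simulate_mk_character(tree, rate_model(c("G", "S"),
                                rates = c(0.6, 0.4)), seed = 8)$char
sample <- emulate_tree_sample(tree, n_trees = 20, length_jitter_sd = 0.1,
                              seed = 9)
irreversibility_test(sample, char)
#> Likelihood-ratio test of irreversible specificity evolution
#>   (mean maximized lnL over 20 tree(s))
#>
#>                         mean lnL
#> G <-> S (bidirectional)  -21.741
#> G -> S only              -22.666
#> S -> G only              -24.954
#>
#>   vs G -> S only  LR =  1.849, p = 0.1739
#>   vs S -> G only  LR =  6.426, p = 0.0112  (one-way model rejected)
```

The three tallies are the number of species called specialist, generalist
and host-unknown among the 37 packaged records. In the simulated example
the character was generated with transitions in both directions, and the
test accordingly rejects the S→G-only model (p = 0.011) while the G→S-only
model cannot be excluded on these data (p = 0.17) — with one 40-tip
character the test has limited power, which is also the situation the
method faces on real host-specificity data.

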