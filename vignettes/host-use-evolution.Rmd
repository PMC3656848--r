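---
title: "Modeling the evolution of host use and host specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of host use and host specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostarrow)
```

## The scientific problem

Cuckoo bees do not provision their own nests; each species exploits the
nests of one or several host bee species. Over a phylogeny of such
parasites two questions arise. First, which hosts did ancestral lineages
use, and how often were new host lineages acquired ("host switches")?
Second, is the evolution of host *specificity* — the specialist versus
generalist strategy — directional (e.g., specialists arise from
generalists but never revert) or flexible? `hostarrow` implements the full
analysis chain for both questions on a user-supplied phylogeny (or a
posterior sample of phylogenies), plus simulators that generate every
input with known truth.

## The Mk model and its likelihood

A discrete character with k states evolves along each branch as a
continuous-time Markov chain with generator Q; the off-diagonal entry
q_ij ≥ 0 is the instantaneous rate of the i→j transition (events per unit
branch length) and the diagonal is minus the row sum, so
P(t) = exp(Qt) is row-stochastic for every t ≥ 0. `rate_model()` carries
the constraint structure: off-diagonal cells are partitioned into
equality classes sharing one parameter, or fixed to zero. One-way
("irreversible") models are zero-fixed cells — there is no
reparameterization trick, and maximum-likelihood estimates for them sit
on the boundary legitimately.

The likelihood of tip data is computed by the pruning algorithm:
per-state conditional likelihoods propagate from the tips to the root in
post-order, partials are rescaled per node to avoid underflow, and the
root combines them with a root prior. Tips with missing data contribute
all-ones partials, i.e., they are marginalized out; the likelihood is
therefore invariant to pruning a missing tip, a property the test suite
checks. The root prior is **uniform over states by default**. This is a
documented assumption, not an estimate: it matches common usage of
BayesTraits-style discrete mapping, and it makes degenerate cases exact
(all rates zero and monomorphic tips give lnL = ln(1/k)). Stationary and
fixed root priors are available through `rate_model(root_prior = )`.

State labels are interned as strings and sorted lexicographically, so a
specialist/generalist character always orders as G = 0, S = 1 regardless
of input order. This convention is fixed for cross-run reproducibility.

Transition matrices use the closed form for k = 2 (the dominant case:
the specificity character and each per-host presence/absence character
are binary) and an eigendecomposition for k > 2, falling back to
scaling-and-squaring when the generator is defective or ill-conditioned.

## Maximum-likelihood rates and tree-file averaging

`fit_mk()` maximizes the pruning likelihood over the free rate classes
with bounded multi-start local optimization: rates live in
[1e-8, 100] events per unit branch length, and L-BFGS-B is started from
five deterministic log-spaced points (0.01 to 10). There is no stochastic
search, so a fit is a pure function of its inputs. Non-convergence is
flagged on the returned object rather than raised.

Phylogenetic uncertainty is handled the way discrete-trait studies based
on a Bayesian "tree file" handle it: `mean_loglik_sample()` fits the
model independently on every tree of the sample and averages the
maximized log-likelihoods. The irreversibility statistic is formed from
these **mean** log-likelihoods,
LR = 2(mean lnL_bidirectional − mean lnL_one-way) — not from per-tree LRs
averaged, which is a different quantity. The LR is referred to the
chi-square distribution with one degree of freedom (the models differ by
one free parameter); `chisq_upper_tail_df1()` is the reference tail.

Two numerical details. Small negative LRs (below 1e-4 in absolute value)
are optimizer noise on the shared boundary and are clamped to zero with a
warning; larger negative values indicate a failed fit and raise an error.
And because the one-way null pins a rate at the boundary of its parameter
space, the plain chi-square(1) reference is conservative; the
theoretically sharper ½χ²₀ + ½χ²₁ mixture is available via
`irreversibility_test(boundary_mix = TRUE)`, but the headline output uses
plain chi-square(1) for fidelity with standard practice in this
literature.

## Specialist/generalist classification

The packaged 37-species host table records, per species, presence of
eight host lineages (two *Lasioglossum* lineages, two *Halictus*
subgenera, *Andrena*, *Colletes*, *Perdita*, *Melitturga* — the eight
collapse to six host genera), the number of distinct host genera, whether
the genera beyond the main one are used only sporadically, and whether
the hosts are ecologically similar. Three graded rule sets convert those
annotations into specialist (S) / generalist (G) calls:

* **Distribution I** (least restrictive): S if the regularly used hosts
  represent a single genus; extra genera are tolerated when sporadic.
* **Distribution II** (the main analysis): as I, plus the requirement
  that all hosts, including sporadic extras, are ecologically similar.
* **Distribution III** (most restrictive): S only for ecologically
  similar hosts of a single genus.

A species with no recorded hosts is `unknown` under every rule set and is
treated as missing data in all downstream characters. On the packaged
table the three rule sets yield 2, 8 and 9 generalists among the 30
species with known host records; the classifier is rule logic and the
table is data, so the same rules apply unchanged to simulated host
tables. The sporadic-use and ecological-similarity annotations are a
curated part of the packaged table (they cannot be derived from the
presence flags alone); `sporadic_extra` with a single recorded genus is a
contradiction and is rejected at validation.

## Ancestral hosts, the PP > 0.7 rule, and switch counting

Ancestral host mapping runs one **independent binary analysis per host
lineage** (presence/absence), rather than one multi-state analysis, so
that several hosts can be supported simultaneously at one ancestral node.
`call_ancestral_hosts()` thresholds the mean posterior probabilities:
a host is called at a node when PP(presence) is **strictly** greater than
0.7 (a posterior of exactly 0.7 is excluded).

A host switch is a **gain relative to the parent**: a lineage present in
a child's host set but absent from its parent's non-empty set. Multiple
gains on one branch count separately; losses are not switches; branches
whose parent set is empty (no host called) carry no information and are
skipped but reported. On simulated host tables the true node sets are
known, and the suite checks that switch detection on the truth recovers
exactly the planted gains.

For parsimony mapping, `fitch_state_sets()` reports per-node **MPR
sets** — the union of states over all most-parsimonious
reconstructions — rather than a single ACCTRAN/DELTRAN resolution,
because ambiguous nodes are themselves a result (ancestral-state studies
report nodes where both states are possible). The implementation is a
unit-cost Sankoff dynamic program, which is exact on hard polytomies
(consensus trees contain them) and under missing data. Change counting
distinguishes branches where every optimal reconstruction changes state
(parent and child MPR sets disjoint) from branches where only some do.

## The reversible-jump MCMC

`run_mcmc()` targets the joint posterior of (rates, rate-model indicator,
hyperprior mean, tree index):

* **Rate proposals** are uniform sliding windows of half-width `ratedev`,
  reflected at zero. `tune_ratedev()` doubles or halves the half-width on
  short pilot chains until the acceptance rate of rate proposals lies in
  the 20–40% window.
* **Hyperprior.** "An exponential prior seeded from a uniform
  hyperprior on [a, b]" is interpreted as: each rate has an exponential
  prior whose mean is itself uniform on [a, b] and is resampled by its
  own Metropolis move. A flat prior on [0, `uniform_max`] is available as
  an alternative (`prior = "uniform"`) and is what the quadrature
  validation test uses, since it makes the posterior an explicit
  two-dimensional integral.
* **Reversible jump.** For a binary character the model space is {equal
  rates, distinct rates}. Dimension moves propose the destination model's
  rates directly from the prior, so the proposal density cancels the
  prior in the acceptance ratio and the move accepts with the bare
  likelihood ratio — a valid independence-sampler RJ step without
  Jacobian bookkeeping.
* **Tree uncertainty.** Each iteration proposes a tree drawn uniformly
  from the sample and accepts it through a Metropolis–Hastings
  likelihood ratio (an unconditional swap would not target the stated
  joint posterior).
* **Node addressing.** Nodes are addressed as MRCAs of tip sets so they
  remain identifiable across topologies; iterations whose current tree
  lacks the tip set as a clade are skipped for that node's summary and
  counted. Fossilizing a node (for Bayes-factor node tests) zeroes the
  partials of all other states at that node in every likelihood
  evaluation; a constraint unplaceable in more than half of the trees is
  an error.
* **Summaries** are taken every 100th post-burn-in iteration (default):
  marginal node-state posteriors by the up–down algorithm on the current
  tree, the visited model frequencies, and the retained log-likelihoods.

The marginal likelihood is estimated by the harmonic mean of the retained
likelihoods, computed stably in log space. The harmonic-mean estimator is
known to be unstable (its variance can be infinite); the implementation
attaches a jackknife standard error so the stability can be inspected,
but the headline statistic remains the plain harmonic mean because that
is the estimator this literature reports. `bayes_factor_2ln()` applies
the conventional 2/6/10 thresholds to 2 ln(BF).

Fossilized-node Bayes factors deserve a caveat the suite makes explicit:
under a wide rate prior, a node fossilized in the "wrong" state can still
reach a likelihood near 1 by proposing a fast transition immediately
above the node, so the Bayes factor is prior-sensitive. The packaged test
of this feature uses a bounded flat prior for that reason.

## The simulators and what passing tests show

`simulate_yule_tree()` grows a pure-birth tree: with k extant lineages
the wait to the next split is Exp(k·λ), so the expected root-to-tip depth
is Σ_{k=2..n} 1/(kλ) — the suite checks this against 500 replicates.
`emulate_tree_sample()` multiplies branch lengths by independent
lognormal factors (meanlog 0), a deliberately simple stand-in for
posterior branch-length variation; it makes no claim to reproduce the
correlation structure of a real MrBayes posterior, and topology is held
fixed. `simulate_mk_character()` simulates the character history
event-by-event (exponential waiting times, not endpoint sampling by
matrix exponentials) precisely so that every true transition has a branch
and time — switch-recovery tests need positions, not just endpoints.
`simulate_host_table()` evolves the eight host lineages independently,
mirroring the per-host analysis design, and derives the specificity
annotations from the realized host counts.

All generators are seeded and byte-reproducible. What passing tests show
is that the machinery is correct **under the Mk model's own
assumptions** — independent lineages, homogeneous rates, correct
topology up to sampled uncertainty. Real host-record data violate these
in known ways (unobserved host associations, host records of uneven
quality, rate variation across clades), so green tests certify the
arithmetic and the algorithms, not the biology.

## Design of the simulation experiments

The suite's statistical experiments use problem sizes chosen to balance
resolution against run time, stated here as the package's own choices:

* **Parameter recovery.** 100 characters generated with rates (2, 5) on
  200-tip pure-birth trees; the generating rates must lie inside the
  central 95% band of the replicate ML estimates. A single character on
  one tree identifies two rates only weakly, so the band is wide — the
  experiment checks calibration, not precision.
* **Size of the irreversibility test.** The test's null hypothesis is the
  one-way model, so the type-I experiment simulates from the fitted null
  family itself: G→S-only characters (rate 0.5, uniform root prior) on
  40-tip trees, keeping polymorphic replicates. Under this boundary null
  the plain chi-square(1) reference over-covers, and the rejection rate
  at α = 0.05 must stay below 0.05 + 3 binomial SE. Two nearby designs
  are deliberately *not* used: generating from a bidirectional model
  measures power (the one-way model is then simply false — rejection
  rates near 1 are correct behavior, not an error rate), and fixing the
  generator's root state while fitting with a uniform root prior
  introduces a misspecification that inflates the rejection rate.
* **Direction sensitivity.** On data generated under an S→G-only regime
  the test rejects the opposite (G→S-only) model more often than the
  model that actually generated the data.
* **MCMC validation.** On a two-tip tree with a flat rate prior the
  posterior is a two-dimensional integral computable by quadrature; the
  chain's node posteriors must match it to 0.02 in sup-norm at 200,000
  iterations. Monomorphic data must pin all nodes to the observed state
  (PP > 0.95, checked with the equal-rates template — under the
  two-parameter template a broad hyperprior legitimately leaves the root
  ambiguous via the fast-transition explanation discussed above).

## Known limitations

* Tree inference is upstream: the package consumes Newick/NEXUS trees and
  never estimates topologies or branch lengths.
* The harmonic-mean marginal likelihood is reported for fidelity with the
  discrete-mapping literature despite its instability;
  stepping-stone/path sampling are out of scope.
* The RJ model space is the two-model space relevant to binary
  characters; general k-state rate-class partitions are fitted by ML
  templates, not explored by RJ.
* Host switches are counted at the host-lineage (genus-group) level;
  switches below that level are invisible by construction.
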