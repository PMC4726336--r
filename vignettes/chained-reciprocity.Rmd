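---
title: "Simulating and analysing chained indirect-reciprocity games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing chained indirect-reciprocity games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainrecip)
```

## The experimental protocol being emulated

A group of N participants (17 or 19 at reference scale) plays a chained
gift-giving game. Five chains run simultaneously; in each chain every
participant acts a fixed number of times (9 at N = 19), each time toward
a different peer, so a participant accumulates 45 decisions ("rounds")
per game. Each decision is binary: donate the endowment (`C`; the
recipient gets double) or keep it (`D`).

The two game types differ only in what the actor is shown and whom they
give to. In the *pay-it-forward* game the actor sees the decision their
upstream neighbour just made toward them and then gives to the next
player downstream. In the *reputation-based* game the actor sees a peer's
decision toward a third party and gives to that observed peer. In the
reputation-based game the actor in a chain's last position is told that
no upstream neighbour exists — nobody will ever act on their reputation —
which empirically depresses cooperation in the final round.

### Schedule construction

Positions must be allocated so that no ordered donor–recipient pair
occurs twice within one chain (this excludes direct reciprocity). We
construct each chain as `decisions` successive cyclic passes over a
random permutation of the group: within a pass the actor index advances
by a fixed step, each pass using a different step drawn (without
replacement) from the residues coprime to N. Every ordered pair then
carries a pass-specific offset and cannot repeat; one extra offset is
reserved for the phantom neighbour off the chain's end (the final
recipient in pay-it-forward, the initial recipient in reputation-based),
which is why `decisions + 1` distinct coprime offsets are required. For
prime N (17, 19) this is exactly the feasibility bound
`decisions ≤ N − 2`; for composite even N fewer offsets exist and the
constructor rejects the configuration as infeasible rather than
attempting an unbounded search. `validate_schedule()` re-checks every
invariant independently and reports violations as data, never as errors.

The lab's exact allocation algorithm is not documented, only its
constraint; the cyclic-pass layout is one admissible constructive choice.
"Rounds" number each participant's decisions across chains in arrival
order, with chains interleaved round-robin — the protocol only fixes
that chains run simultaneously, so lockstep interleaving is the package's
choice. Per-decision three-letter pseudonyms are sampled globally
without replacement from the 26³ alphabet, which implies both anonymity
rules (fresh name after every decision, disjoint names across chains).

## The generative behaviour model

Each decision is Bernoulli with a logistic probability:

$$\operatorname{logit} q_{ij} = \beta_0 + r_i + \beta_{\text{prev}} x_{\text{prev}}
 + \beta_{\text{round}}\, j + \beta_{\text{p}\times\text{r}}\, x_{\text{prev}} j
 + \beta_{\text{svo}} s_i + \beta_{\text{gender}} g_i + \text{offsets},$$

with $x_{\text{prev}} \in \{0, 1\}$ the observed previous decision,
$j \in \{1, \dots, 45\}$ the raw (uncentred) round, $s_i$ an indicator of
a pro-social value orientation, $g_i$ of male gender, and
$r_i \sim N(0, \sigma^2)$ a per-participant random intercept.

Parameters that matter, with defaults:

| parameter | units | default | rationale |
|---|---|---|---|
| preset coefficients | log odds | `log()` of the published per-game odds ratios | anchors the simulator to the reported effect sizes |
| `beta_no_info` | log odds | 0 | chain-first decisions have no observable prior; the previous-decision terms are simply omitted |
| `beta_terminal` | log odds | −2 | reproduces the last-round cooperation drop of the reputation game; no coefficient is reported for it, so the size is a package choice |
| `intercept_sd` | log odds | 1.5 | the source regression table omits the random-intercept variance; 1.5 gives per-participant cooperation rates spanning roughly 0.1–0.9, matching the large between-participant spread visible in the study's scatter plots |
| SVO mix | proportions | 80/35/16 over 131 | the study's classification counts |
| gender mix | proportions | 0.5/0.5 | not reported; an uninformative default |

Unclassified participants score 0 on the SVO covariate (like pro-self)
but remain identifiable in rosters so analyses can exclude them.
Random intercepts are frozen across the two games by default
(`shared_intercepts = TRUE`), which induces the between-game correlation
of per-participant cooperativeness; setting it to `FALSE` redraws them
per game and removes that correlation.

### What the generator emulates, and what it does not

It emulates: the chain structure and information flow of both protocols,
effect sizes pinned to the published per-game regressions, stable
individual differences, the terminal-information drop, and study-scale
group composition (six groups of 19 plus one of 17 = 131 participants).
It does **not** emulate: learning or strategy updating within a game,
emotion dynamics, order effects between games (the order is recorded but
behaviourally inert), group-level random effects, dropouts/technical
truncations, or any dependence beyond the observed previous decision.
Passing tests therefore demonstrate internal consistency of the pipeline
and fidelity to the published effect sizes — not that human behaviour
follows this model.

### A deterministic oracle

`expected_cooperation()` computes the model-implied aggregates without
simulation: a forward dynamic-programming pass over each chain propagates
the probability that the running decision is `C` and accumulates expected
counts of every (observed, own) pair. Simulation is tested to recover
these values within Monte-Carlo error; the two code paths share only the
linear predictor.

## Reciprocity statistics

`cooperation_counts()` tallies the four (observed, own) cells; decisions
without an observable prior count toward `p(C)`'s numerator/denominator
but toward no conditional cell (the same convention is used for the
per-round `p(C)` series — the protocol leaves this open and the package
includes them). `p(C|C)`, `p(C|D)` and the reciprocity score
`R = p(C|C) − p(C|D)` are undefined (NA) whenever a conditioning count is
zero — never coerced to 0 — and such participants are dropped pairwise
from means and correlations.

Per-round series use the normal approximation `mean ± 1.96 × SE` with the
sample standard deviation of the pooled 0/1 outcomes, no continuity
correction. Between-game correlation of a conditional probability is
also reported after residualising: within each game the conditional is
regressed on `p(C)` by least squares and the residuals are correlated
across games. The conditional is the dependent variable — the residual
is "the reciprocal tendency not predicted by unconditional cooperation".
Residual vectors with (numerically) zero variance, as produced by an
exactly linear relationship, yield NA rather than a spurious
correlation.

## Run-length contagion analysis

Run lengths of consecutive identical decisions are extracted per chain
(`rle` within chain; runs never cross chain boundaries) and the first and
last run of each chain are flagged censored — truncated by the boundary
rather than ended by the opposite decision. Censored runs are *included*
by default in fits and tests, the simplest reading of the original
analysis; `censoring = "exclude"` drops them, and its effect is visible
in the fit objects.

Both null models give geometric run lengths $P(k) = p^{k-1}(1-p)$:

- **i.i.d.**: the continue probability for C-runs is the overall
  cooperation fraction (deliberately *not* the run-based MLE, which
  would equal the Markov self-transition estimate); D-runs use its
  complement.
- **two-state Markov**: C-runs continue with $\hat p(C|C)$, D-runs with
  $1 - \hat p(C|D)$, estimated from the observed transitions.

Fits pool runs across all chains and groups of a game, and are invariant
to chain processing order. Degenerate logs (all-C or all-D) are rejected
explicitly since the geometric parameter must lie in [0, 1).

### Goodness of fit

The KS statistic is the sup distance between the run-length ECDF and the
geometric CDF over the integer support `1..max(runs)` (beyond which the
discrepancy can only shrink). Two p-values are available:

- `asymptotic`: the classical Kolmogorov series, as standard KS software
  would report; it ignores the discreteness of the support and the fact
  that the parameter was estimated.
- Monte-Carlo. Here the package distinguishes two situations. For a
  *known* parameter, `ks_geometric(..., method = "monte_carlo")`
  resamples run sets from the geometric itself; its p-values are uniform
  under the null. For a model *estimated from the same log* — the usual
  case — `ks_fit()` runs a chain-level parametric bootstrap: every
  replicate resimulates all chains at their original lengths from the
  fitted decision process (realised as alternating geometric runs
  truncated at chain boundaries, started from the stationary
  distribution), re-applies the censoring rule, re-estimates the model
  with the same estimator, and recomputes D. This accounts for
  discreteness, boundary censoring *and* parameter estimation; run-level
  shortcuts do not (fixing the parameter is conservative, refitting a
  run-based MLE against a fraction-based estimate is anticonservative —
  both were measured during development and rejected). At the study
  condition (chains of 171 i.i.d. decisions) the bootstrap's type-I
  error is at its nominal 5% level.

Monte-Carlo p-values use the `(exceedances + 1)/(B + 1)` correction and
are therefore never exactly zero.

## Problem sizes and numerical choices

The test suite works at the study scale (19 × 5 × 9 = 855 slots per
game) and uses 50 simulation replicates for recovery checks, 1000
chains for KS calibration and 25 for power, with 199 bootstrap
replicates per test — sizes chosen so the whole suite runs in about two
minutes while leaving Monte-Carlo bands far wider than the observed
margins. A full default-scale experiment (7 groups × 2 games) runs in
about one second. All randomness flows from explicit seeds; the master
seed of `run_experiment()` derives per-stage seeds through a small
deterministic hash, so reports are bit-reproducible.

## Known limitations

- The chain constructor requires `decisions + 1` coprime step offsets,
  which is tight only for prime group sizes; unusual composite sizes may
  be rejected although some valid layout exists.
- The behaviour model is first-order: dependence beyond the immediately
  observed decision (e.g. on one's own history) is out of scope.
- The asymptotic KS p-value inherits the usual continuous-case bias on
  discrete data; it is retained because it mirrors what standard
  software reports, but `ks_fit()`'s bootstrap should be preferred for
  inference.
- Group-size-17 chain length is configurable (default 8 decisions per
  chain) since the original per-group chain lengths are not public.
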