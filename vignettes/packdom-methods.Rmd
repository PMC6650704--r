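---
title: "Methods: dominance hierarchies, ERGMs and rank-resolved goodness of fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance hierarchies, ERGMs and rank-resolved goodness of fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packdom)
```

packdom analyses agonistic-interaction data from a social group — the
motivating system is a free-living dog pack of 27 individuals with a
sex–age-graded hierarchy — through four connected stages: network
construction, ordinal rank inference, exponential random graph
modelling of binary and count-valued networks, and a simulation-based,
rank-resolved goodness-of-fit surface that localises where in the
hierarchy the fitted model fails to predict who initiates
interactions. This vignette documents the models, their assumptions,
the tunable parameters, and the numerical design choices.

## Data model and networks

The raw input is an event log: one row per observed agonistic event
with an initiator, a receiver and a behavioural category (submissive,
ritualized dominance, or aggressive). From one log the package builds,
per behaviour, a directed weighted network (entry $y_{ij}$ = number of
events initiated by $i$ towards $j$), its binary indicator, and an
undirected weighted network ($y_{ij} + y_{ji}$, the total interaction
frequency of the pair). Node order is fixed lexicographically by id,
and individuals with no events of a behaviour remain as isolates, so
that models of the three behaviours share one node set and are
directly comparable. Self-loops are structurally excluded.

## Rank inference (I&SI)

Ranks are inferred from submissive interactions only, on the premise
that submission is the least ambiguous winner/loser marker in canids:
the *recipient* of a submissive act is credited with the win. Given
the wins matrix, an ordering is sought that minimises,
lexicographically, the number of inconsistent dyads $I$ (a dyad where
the lower-ranked member holds strictly more wins; ties and silent
dyads are never inconsistencies) and then the summed rank differences
of those dyads, $SI$.

The search is a deterministic hill climb from the descending David's
score order (ties broken by total wins, then id): each sweep visits
every currently inconsistent dyad and trials (a) swapping its two
members and (b) relocating the winner to just above the loser, keeping
any move that lowers $(I, SI)$; when no such move exists an
adjacent-swap polish pass runs, and the search stops at a fixed point.
Because hill climbs can stall, three additional seeded random restarts
are run by default and the best result kept. On packs of up to eight
individuals the test suite verifies the attained $(I, SI)$ against
exhaustive enumeration of all orderings; for a 27-individual pack the
search space is astronomically larger, and optimality is heuristic, as
it is for every I&SI implementation in practice.

Two caveats follow from the objective itself. The optimum need not be
unique: dyads with no data do not constrain their relative order, so
under sparse observation adjacent individuals can be exchangeable (the
generator tests therefore only demand exact recovery under full dyad
coverage). And $I = 0$ implies $SI = 0$ by construction.

## Exponential random graph models

Both response types put an exponential-family tilt on a reference
distribution over networks with fixed node set:
$P_\theta(Y = y) \propto h(y)\,\exp\{\theta \cdot g(y)\}$, with
$h \equiv 1$ for binary networks and the Poisson reference
$h(y) = \prod_{ij} 1/y_{ij}!$ for count networks, so that a count
model with only the `sum` term is i.i.d. Poisson on dyads.

The term vocabulary covers: `edges`/`sum`; `mutual` (reciprocated
dyads — binary directed models only: in count models reciprocity terms
prevented convergence of the valued fits, so they are refused);
`transitive` (ordered triples $i{\to}j$, $j{\to}k$, $i{\to}k$) and
`cyclical` (distinct 3-cycles) for binary networks; their valued
generalisation by the min-within-path, max-over-paths transform
$\sum_{(p,q)} \min\{y_{pq}, \max_m \min(y_{pm}, y_{mq})\}$ (and the
cyclical analogue closing $q \to p$); `nodematch(attr, level)`;
directed class-mixing `nodemix(attr, from, to)`; `sender`, `nodecov`
and `absdiff` covariates. On count networks attribute terms are
weight-multiplied. "Interactions: X versus Y" effects can be expressed
either as mixing terms (default) or as sender covariates — both
readings are defensible, so the choice is a configuration switch.

### Estimation

Fitting starts from the maximum pseudolikelihood estimate. For binary
models this is the classical logistic regression of each dyad's state
on its change statistics. For count models the package maximises the
exact product of full-conditional masses: each dyad's conditional is
evaluated on a truncated support $0..v_{\max}$ (with $v_{\max}$ at
least three times the largest observed count plus 15, so the truncated
tail is numerically negligible for any non-degenerate fit), by BFGS
with the analytic score, with standard errors from the observed
pseudo-information. Aliased or information-free terms (for example a
constant rank covariate) are detected and refused with the term named.

`method = "mcmle"` (the default) refines the MPLE by Monte-Carlo
maximum likelihood: networks are simulated at the current $\theta$,
and $\theta$ is updated by a damped Newton step using the simulated
mean and covariance of $g$ — the exponential-family score and Fisher
information. Each step is halved until the importance weights it
implies retain an effective sample size of at least 20% of the
simulated sample, which prevents the unbounded steps that occur when
the observed statistics fall outside the simulated convex hull.
Convergence is declared when every term's simulated mean is within
`tol` (default 0.1) simulation standard deviations of its observed
statistic; a degeneracy guard aborts when a statistic drifts away from
its observed value by more than 5 SD without improving over successive
iterations, or freezes at a boundary. Standard errors are
$\sqrt{\mathrm{diag}(\hat V^{-1})}$ with $\hat V$ the simulated
covariance at the final $\theta$; for dyad-independent models MPLE is
the exact MLE and the two estimators agree within Monte-Carlo error
(this is tested).

### Simulation

Binary networks are sampled by Metropolis–Hastings over uniformly
chosen single-dyad toggles with acceptance
$\exp(\theta\cdot\delta)$. Count networks are sampled by random-scan
Gibbs: the chosen dyad is redrawn from its full conditional under the
Poisson reference, evaluated on $0..v_{\max}$. The Gibbs form was
chosen after measuring the mixing of ±1 increment/decrement proposals
on 27-node count networks: a dyad holding count $c$ needs on the order
of $c^2$ visits to forget its state, so the retained-sample effective
size collapses to a tiny fraction of the draws, which in turn
destabilises estimation. A full-conditional redraw costs about the same as one
increment proposal — the valued triad terms admit an
$O(n^2 + n\,v_{\max})$ profile of the statistic in the dyad's value —
and refreshes the dyad completely.

The default interval between retained draws is one expected sweep of
the free dyads ($n(n-1)$ directed, half that undirected), the smallest
interval at which consecutive retained draws can be nearly
independent; the test suite checks that the lag-1 autocorrelation of
retained statistics stays below 0.5. Burn-in defaults to $10^4$
updates (≈ 14 sweeps for a directed 27-node network). All samplers run
on R's RNG, so a seed makes every fit, ensemble and pipeline run
exactly reproducible; ensembles never mutate their template network.

## Rank-resolved goodness of fit

For the directed weighted dominance and aggression networks, the
directed rank model (`sum` + valued transitive and cyclical terms + a
sender rank covariate) is fitted and used to simulate an ensemble of
1000 networks. For every dyad with at least one observed interaction,
orient the pair by the more dominant member and let $p$ be the
proportion of its events initiated by that member. The per-dyad
goodness of fit is the median, over the simulated networks in which
that dyad interacted at all, of $p_{\mathrm{obs}} - p_{\mathrm{sim}}$:
positive values mean the dominant individual initiates more than the
model expects, negative values less. Dyads silent in the observed
network — or in every simulation — are flagged undefined rather than
imputed, and dyads defined in under 5% of simulations are flagged
low-support.

The surface is summarised over (hierarchy position, rank difference),
where a dyad's position is the mean of its two ranks (minimum rank is
available as an alternative; the axis construction is not uniquely
determined by the source material, and the mean is the symmetric
choice). The median is taken over signed differences, preserving the
direction of misfit. Because ranks derive from submissive data, the
rank models and the surface are never computed for the submissive
network — the fit would be circular, and the functions refuse it.

`instability_summary()` contrasts mean $|$gof$|$ inside a named band —
by default dyads whose position lies in the central third of ranks and
whose rank difference is between 2 and 4, the "close but not
adjacent, centrally placed" region — against all other defined dyads,
with a permutation p-value from shuffling band labels across dyads.

## The synthetic pack generator

The generator exists so that every stage is testable without the
original field data, and its defaults describe the study conditions
the analyses assume. A pack (default composition 6 adult M, 5 adult F,
4 subadult M, 1 subadult F, 6 juvenile M, 5 juvenile F; N = 27)
receives a latent hierarchy graded age class over sex: adults above
subadults above juveniles, males above females within an age class,
random order within each sex–age cell.

For each unordered dyad and behaviour, the event count is Poisson with
log-rate `log(base)` plus `top_rank_gradient` times the dyad's
proximity to rank 1, and — for aggression only — `centre_aggression`
times proximity to the hierarchy centre plus a close-rank elevation of
`close_rank_aggression × (1 − (Δ − 1)/k_max)` (full for adjacent
dyads, declining log-linearly with rank difference Δ at the
close-rank scale `k_max`), emulating the observed concentration of
aggression among central, closely ranked individuals. Each event's
initiation follows the hierarchy with probability
`plogis(steepness × rank difference)` (the dominant initiates
dominance/aggression; the subordinate initiates submission). For
unstable dyads — rank difference between 2 and `k_max = 4` with mean
rank in the central third — that probability is shrunk towards 1/2 by
the `instability` factor.

Default values: `steepness = 1` (adjacent dyads ≈ 73/27 initiation
asymmetry, ranks five apart ≈ 99/1 — a clear but imperfect hierarchy);
base rates of 1.5/1.0/0.8 expected events per dyad for
submissive/dominance/aggressive behaviour, putting behaviour totals in
the hundreds for a 27-dog pack, the order of magnitude of a year-long
observational study; gradients 0.8/0.6/0.6; `instability = 0.5`. The
generator reproduces the qualitative regime the analyses were built
for — it is not a fit to the field data, whose event totals were not
published. What it deliberately omits: temporal and seasonal dynamics,
observation-effort heterogeneity, relatedness structure, and
context-specific behaviour. Passing tests therefore demonstrate that
the pipeline recovers known structure of this generating process, not
that the field study's exact coefficients are reproduced.

`recovery_experiment()` runs the full loop (generate → rank → fit →
simulate → surface → band contrast) over replicates and reports rank
recovery (Spearman), fitted coefficient signs, and the in-band versus
out-of-band misfit contrast, flagging rather than dropping failed
replicates.

## Numerical choices and problem sizes

* Count full conditionals and the count pseudolikelihood are evaluated
  on a truncated support; the cap is far above any observed count and
  interacts only with degenerate parameter regions, which the
  degeneracy guard reports anyway.
* The MC-MLE covariance is ridge-stabilised ($10^{-8}$ relative) only
  if numerically singular.
* Permutation p-values use the add-one estimator, so they are never
  exactly zero.
* Effective sample sizes use the initial-positive-sequence
  autocorrelation estimator; Geweke z compares the first 10% with the
  last 50% of each retained chain.
* The test suite runs its verification at sizes chosen to exercise the
  full pipeline in minutes: exhaustive I&SI checks at n = 6–7,
  triad-statistic oracles at n ≤ 10, MC-MLE fits with 400–1000
  retained networks, goodness-of-fit ensembles of 1000 networks, and
  20-replicate recovery experiments.

## Known limitations

* The exact term combinations of the original field analysis this
  package emulates were not published in full; the implemented
  vocabulary covers every reported term family, and the pipeline's
  default model matrix is an approximation at that level.
* MC-MLE standard errors ignore the (small) Monte-Carlo contribution
  beyond the simulated-information inverse; the diagnostics report the
  per-term MC standard errors separately.
* I&SI optimality is heuristic beyond exhaustive-search sizes.
* Count models assume the Poisson reference; over- or under-dispersed
  alternatives are out of scope.
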