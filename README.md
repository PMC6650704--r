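# packdom

Analysis of dominance hierarchies from agonistic-interaction networks
in social animal groups, built around the study design of a free-living
dog pack: 27 individuals, three behavioural categories (submissive,
ritualized dominance, aggressive), and the question of *where in a
hierarchy* dominance relationships are stable and where they are not.

It is aimed at behavioural ecologists and animal-social-network
analysts who have event-level interaction logs (initiator, receiver,
behaviour) and want a reproducible pipeline from raw events to
rank-resolved hierarchy diagnostics.

## What it computes

1. **Networks.** Per behaviour: directed weighted, directed binary and
   undirected weighted networks over a fixed node set (isolates kept).
2. **Ranks (I&SI).** An ordinal dominance order from submissive
   interactions (the recipient of submission is the winner),
   minimising lexicographically the number of inconsistent dyads *I* —
   dyads where the lower-ranked member holds strictly more wins — and
   then their total strength *SI* (summed rank differences),
   initialised from David's scores `w + w2 − l − l2`.
3. **ERGMs.** Exponential random graph models
   `P(Y = y) ∝ h(y) exp{θ·g(y)}` for binary (`h ≡ 1`) and count
   networks (Poisson reference `h(y) = Π 1/y_ij!`), with structural
   terms (edges/sum, mutual, transitive and cyclical triads, and their
   valued min-max-min generalisations) and attribute terms (nodematch,
   directed class mixing, sender/node/absdiff covariates). Estimation
   is maximum pseudolikelihood refined by Monte-Carlo maximum
   likelihood with convergence and degeneracy diagnostics.
4. **Rank-resolved goodness of fit.** From a fitted rank model, 1000
   simulated networks; per dyad, the median difference between the
   observed and simulated proportions of interactions initiated by the
   more dominant member, mapped over hierarchy position × rank
   difference, with an in-band/out-of-band permutation contrast that
   localises hierarchy instability (e.g. central, close-but-not-adjacent
   dyads).
5. **Synthetic packs.** A generator with a sex–age-graded latent
   hierarchy, rank-graded interaction rates, centrally concentrated
   aggression and tunable central-band instability, plus
   parameter-recovery experiments over the full pipeline.

## Worked example

```r
library(packdom)

pack  <- make_pack(seed = 42)                      # 27 dogs, graded hierarchy
log   <- simulate_interactions(pack, pack_params(seed = 42))
ranks <- isi_rank(wins_matrix(log, pack$attrs), seed = 1)

net <- build_network(log, "submissive", weighted = FALSE, attrs = pack$attrs)
fit <- packergm(net ~ edges + mutual + transitive + cyclical,
                control = ergm_control(seed = 1))
summary(fit)

dnet <- build_network(log, "dominance", attrs = pack$attrs)
rfit <- fit_directed_rank_model(dnet, ranks, control = ergm_control(seed = 2))
sims <- simulate(rfit, nsim = 1000, seed = 3)
surf <- gof_surface(dnet, sims, ranks)
inst <- instability_summary(surf, central_band(27), c(2, 4), seed = 4)
```

which prints (abridged):

```
<interaction_log> 2273 events among 27 individuals
  submissive: 793, dominance: 511, aggressive: 969
<isi_rank> 27 individuals: I = 2, SI = 5 (3 sweeps, 3 restarts)
MCMC-MLE binary-response model of submissive interactions
       term estimate std_error     z p_value sig
      edges   -0.775     0.844 -0.92  0.3582
     mutual   -0.705     0.400 -1.77  0.0775
 transitive    0.130     0.038  3.38  0.0007 ***
   cyclical   -0.688     0.105 -6.55  0.0000 ***
moment condition: max |z| = 0.038 over 24 iterations
in-band mean |gof| 0.254 vs out-of-band 0.047 (perm p = 0.001)
```

Reading the output: the submissive network is strongly hierarchical —
transitive closure is favoured (+0.130), cycles (−0.688) and
reciprocated submission (−0.705) suppressed. The ranking reproduces
the latent order up to two weak dyads (I = 2). And because this
generator run injects instability into the central band (the default),
initiation direction there departs from the fitted rank model about
five times more than elsewhere (mean |gof| 0.254 vs 0.047, permutation
p = 0.001) — the rank-resolved misfit surface localises exactly the
instability that was built in.

The full pipeline (all networks, models, surfaces, exports, manifest)
runs from one seeded config:

```r
run_pipeline(pipeline_config(seed = 1, outdir = "out", generator = list()))
```

or from the shell via `inst/scripts/packdom-run.R`. See the methods
vignette (`vignettes/packdom-methods.Rmd`) for the models, their
assumptions and the numerical design choices.

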