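# nudgenet

Simulation and analysis of a repeated **question/expert communication game**
on a 25-player network — the setting used in experimental studies of whether
a one-off, non-binding suggestion ("nudge") of communication partners can
seed lasting cooperation. The package is aimed at researchers in behavioural
and network science who want to re-run the computational side of such an
experiment: the exact game mechanics, the suggested network, the
expected-profit theory, calibrated synthetic sessions, and the behavioural
metrics, without access to a laboratory.

## The game and the model

Each round, a uniform random cyclic assignment gives every player a unique
question and a unique expertise, so the *expert-of* relation is a single
25-cycle with pair marginal `P(expert(x)=y) = 1/24`. Players pay 1 ECU per
stage-1 inquiry (which reveals their question and expertise to one receiver)
and 1 ECU per stage-2 reply; truthfulness restricts each reply to one legal
type (self-expert, referral, or "I don't know" when nothing informative is
available). Learning who your expert is earns 10 ECU.

The theory layer computes, **exactly**, the expected group profit of any
directed inquiry network `A` under a reply rate `r` (each available informed
reply sent independently with probability `r`):

```
P(i informed | expert = j) = 1 − (1 − A_ji)(1 − r A_ij) Π_{m∉{i,j}} (1 − r A_im A_jm)
E[replies by m]            = r/(N−1) · Σ_{x: A_xm = 1} indeg(m)
profit                     = Σ_i [ 10·P(i informed) − outdeg(i) − E[replies by i] ]
```

averaged over the cyclic assignment via the `1/(N−1)` marginal (an `O(N³)`
closed form, proven against exhaustive enumeration in the tests). Ensembles
of uniform random digraphs at fixed total volume reproduce the model's two
anchors: the profit-maximising volume of about **4.5 inquiries per player**
at `r = 1`, and the **~50% reply rate** below which no volume is profitable.

The nudge is a fixed 6-regular, diameter-two, vertex-transitive graph on
5×5 group/index labels; full compliance with it informs every player every
round and is worth 2.50 ECU/player/round at `r = 1`.

## Worked example

```r
library(nudgenet)

net <- build_suggested_network()
graph_diagnostics(net)$diameter
#> [1] 2

# expected-profit anchors (Fig.-1-style curves)
cur <- ensemble_curve(0:192, reply_model(1), n_networks = 100, seed = 11)
optimal_inquiries(cur)$per_player
#> [1] 4.48
reply_rate_threshold(0.05, 0:192, n_networks = 100, seed = 11)$threshold
#> [1] 0.5

# a calibrated nudged session and its analysis
log <- simulate_session(session_spec(73, nudged = TRUE,
                                     policies = nudged_policy(),
                                     seed = 1103, label = "N1"))
s <- session_summary(log)          # window: rounds 1-51
round(mean(s$per_round$mean_inquiries), 2)
#> [1] 3.62
round(reply_share(log)$share, 3)
#> [1] 0.858
dec <- link_decomposition(log, net)
early <- dec[dec$round <= 5, ]
round(sum(early$suggested_bi + early$suggested_uni) / sum(early$total), 2)
#> [1] 0.91   # adherence while the stars are shown
```

The numbers mean: the suggestion graph connects any two players within two
hops; on random networks with everyone replying, group profit peaks at ~4.5
inquiries per player and replying must exceed ~50% to be profitable at all;
the synthetic nudged session sends 3.6 inquiries/round, replies to 86% of
its informed-reply opportunities, and aims 91% of its early inquiries along
suggested links — all inside the ranges reported for the lab sessions.

The full analysis pipeline lives in `analysis/01_suggested_network.R`
through `analysis/04_session_metrics.R`; each script narrates its findings
and writes its tables under `results/`.

## Layout

- `R/` — game engine, suggestion graph, expected-profit model, session
  generator, metrics, serialization
- `analysis/` — numbered narrative drivers over the package
- `vignettes/nudged-cooperation-model.Rmd` — the model, its assumptions and
  the design choices, in detail
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  enumeration oracles
- `inst/extdata/` — two small deterministic fixture sessions (regenerable
  via `make_fixtures()`)
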