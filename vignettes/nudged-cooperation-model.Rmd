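---
title: "The question/expert game: model, suggestion graph, and synthetic sessions"
author: "nudgenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The question/expert game: model, suggestion graph, and synthetic sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nudgenet)
```

# The game

Twenty-five players repeatedly search a communication network for help. At
the start of each round every player receives a unique *question* and a
unique *expertise*, drawn so that each question matches exactly one other
player's expertise. Formally, a uniform random permutation $p$ of the players
and a uniform random permutation $q$ of the first $N$ letters are drawn;
player $p_i$ holds question $q_i$ and expertise $q_{i+1 \bmod N}$. The
induced *expert-of* relation is therefore a single $N$-cycle with no fixed
point, and its pair marginal is
$P(\text{expert}(x) = y) = 1/(N-1)$ for every $y \neq x$ — the fact on which
all of the exact expectations below rest.

A round has two stages. In stage 1 a player may send *inquiries* (cost 1
ECU each), which reveal the sender's question and expertise to one receiver.
In stage 2 a player may answer each inquiry received with a *reply* (cost 1
ECU). Because no false content can be sent, exactly one reply type is legal
per inquiry: *self-expert* when the responder's expertise answers the
inquirer's question, a *referral* naming the third player whose own inquiry
revealed the matching expertise, and the *uninformed* reply only when no
informative option exists. A player who learns who their expert is — from
the expert's own inquiry, a self-expert reply, or a referral — earns the
reward of 10 ECU. The 100 ECU endowment is bookkeeping and never enters
reported profit.

`resolve_round()` enforces legality, settles the per-player ledger
$\Delta\pi_i = 10\cdot\mathbf 1[\text{informed}_i] - \#\text{inquiries}_i -
\#\text{replies}_i$, and records *reward attribution*: when $k$ distinct
senders inform the same player in one round, each is credited $10/k$ ECU.
Attribution is bookkeeping for link-level return-on-investment metrics; the
informed player always receives the full reward. Messages from both stages
pool into one equal split, and a redundant self-expert reply (one whose
content the reciprocal inquiry already revealed) still counts as informing,
since its content does identify the expert; metrics that want to exclude
redundant messages can do so explicitly.

# The suggestion graph

The nudge shown in treated sessions is a fixed 25-node graph. Players are
split into five groups of five and indexed $(g, i) \in Z_5 \times Z_5$
(0-based internally; player id $5g + i + 1$). Node $(g,i)$ links to

* $(g,\, i \pm 1)$ — the within-group ring, and
* $(g+1,\, 2i+1)$, $(g+2,\, 3i+3)$, $(g+3,\, 2i+4)$, $(g+4,\, 3i+2)$,

all indices mod 5. The four inter-group rules form two reciprocal pairs, so
the relation is symmetric by construction (the constructor still verifies
it). The result is 6-regular with diameter two and vertex-transitive: the
affine index maps realise an automorphism carrying any node to any other.
The published description uses representatives $1..5$ with $4+2 = 1 \bmod 5$;
the 0-based residues used here are affine-equivalent, and the test suite
checks the resulting neighbour sets directly.

Diameter two plus bi-directionality is what makes full compliance
informative: if every suggested link is used in both directions, every
player's expert is either a direct inquirer or shares an inquiry target able
to refer, so at reply rate one every player is informed every round.

# The expected-profit model

The behavioural model has a single parameter, the reply rate
$r \in [0,1]$: every informed reply a player *could* send is sent
independently with probability $r$, and uninformed replies are never sent.
On a fixed directed inquiry network $A$ ($A_{ij} = 1$ iff $i$ inquires $j$),

$$P(i \text{ informed} \mid \text{expert} = j) =
 1 - (1 - A_{ji})(1 - r A_{ij}) \prod_{m \notin \{i,j\}} (1 - r A_{im} A_{jm}),$$

averaged over the cyclic assignment through the $1/(N-1)$ pair marginal. The
expected number of replies by $m$ is
$\frac{r}{N-1}\bigl(\mathrm{indeg}(m)^2 - \epsilon \sum_x A_{xm}A_{mx}\bigr)$
with $\epsilon = 1$ in the exclude-redundant variant, because each received
inquiry gives $m$ an informative option exactly when $m$ is the expert
(probability $1/(N-1)$) or the expert is one of $m$'s other inquirers
(probability $(\mathrm{indeg}(m)-1)/(N-1)$). Every term involves a single
(player, expert) pair, so the marginal is exact, not an approximation; the
computation is $O(N^3)$ and the test suite proves it equal (to $10^{-9}$) to
exhaustive enumeration over all cyclic assignments and reply-coin outcomes
on every digraph with $N \le 4$ and at most five edges.

Both reply variants are exposed because the published benchmark curve does
not say whether redundant replies are priced; at full compliance they differ
by 0.25 ECU/player/round (2.50 vs 2.75 at $r = 1$).

The *ensemble* layer reflects that the model abstracts from network
structure: for each total inquiry volume $T$ it draws networks with exactly
$T$ distinct directed edges uniform over the $N(N-1)$ ordered pairs and
averages the exact expectation across the draws. Conditioning on total
volume matches the volume axis the curves are plotted against; the grid runs
0 to $192 = 8 \times 24$ total inquiries. Two anchors summarise the curves
under the default economy (reward 10, unit costs, $N = 25$, 100 networks
per volume): at $r = 1$ the mean curve peaks near 4.5 inquiries per player,
and scanning $r$ in 5-point steps the maximal mean profit first turns
positive at $r = 0.50$. At $r = 0$ the expectation is exactly linear,
$T(10/24 - 1)$, independent of structure — a useful closed-form check. Note
that even at $r = 0$ the reward term is present (the expert's own inquiry
informs); "no replies" is not "pure cost".

```{r anchors, eval = FALSE}
cur <- ensemble_curve(0:192, reply_model(1), n_networks = 100, seed = 1)
optimal_inquiries(cur)$per_player        # ~4.5
reply_rate_threshold(0.05, 0:192, 100, seed = 1)$threshold  # 0.50
```

# The synthetic session generator

The generator stands in for the lab subjects so the analysis pipeline can be
exercised end to end. It is a behavioural stand-in, not a fitted model; its
defaults encode the published regularities of the four sessions:

| parameter | baseline | nudged | what it targets |
|---|---|---|---|
| `mean_inquiries` | 2.65 | 3.53 | inquiries/player/round, window 1–51 |
| `reply_rate` | 0.85 | 0.85 | share of informed replies sent (0.81–0.87) |
| `uninformed_reply_rate` | 0.03 | 0.03 | ~3% of possible uninformative replies |
| `redundant_reply_rate` | 0.75 | 0.75 | ~75% of redundant opportunities |
| `reciprocity_weight` | 2 | 2 | preferential, reciprocal partner choice |
| `suggestion_adherence` | — | 0.935 | 91–96% of inquiries on starred links, rounds 1–5 |
| `adherence_after` | — | 0.485 | 44–53% afterwards |

Mechanics and the reasoning behind the open choices:

* **Inquiry counts** are truncated Poisson on $[0, N-1]$ — the published
  record gives only means, and a Poisson count is the least-structured
  choice for "how many partners do I contact this round". The distribution
  is isolated in one helper and swappable.
* **Target choice** weights candidate $t$ by
  $w^{\#\text{messages received from } t}$ with $w$ the reciprocity weight,
  counting *both* replies and inquiries received. Replies alone cannot
  create mutual links ($B$ replying to $A$ raises $A$'s weight for $B$, but
  nothing ever raises $B$'s weight for $A$), whereas subjects demonstrably
  read received inquiries as relationship signals; counting them makes
  mutual inquiry pairs form and persist, which is the reciprocity
  regularity the generator must show. With $w = 1$ targeting is uniform
  (verified by a goodness-of-fit test).
* **Adherence** is a pool choice per inquiry: with the adherence
  probability the target is drawn from the starred partners, otherwise from
  the rest (falling back when a pool is exhausted), so the realised
  suggested-link share tracks the parameter regardless of the reciprocity
  weights inside each pool. The decay after the nudge is removed is a
  *step* at round 6 — the published decomposition shows a sharp drop there
  and a fairly constant share afterwards, so a gradual decay would add a
  parameter the data does not ask for. The preset values 0.935/0.485 sit at
  the centres of the printed ranges after accounting for pool spillover
  when a player sends more than six inquiries.
* **Policies are homogeneous** across players; per-player heterogeneity is
  supported by passing a list of policies but is deliberately uncalibrated
  (no per-subject parameters are published).

What passing the calibration tests does *not* show: real subjects differ
across individuals, learn within a session (round-1 volumes differ from
later rounds), and choose partners for reasons beyond reciprocity and the
nudge. The generator reproduces session-level aggregates, not individual
behaviour, so conclusions about mechanisms in real data still require the
deposited sessions, which the schema-mapped loader ingests.

# Numerical and interface choices

* Attribution fractions are stored as `reward / n_senders` with the integer
  `n_senders` kept alongside, so RRI sums can be audited; conservation
  (attributed reward = reward × informed events) is tested exactly.
* Bi-directionality of a link is defined within a single round
  (simultaneous reciprocal inquiries), matching the per-round
  decomposition; cross-round reciprocity is a different notion and is
  deliberately not conflated with it.
* The reciprocity null holds each player's out-degree fixed and draws
  targets uniformly without replacement, giving
  $\sum_{a<b} k_a k_b/(N-1)^2$ expected mutual pairs; the closed form is
  checked against exhaustive enumeration for $N \le 4$ and Monte Carlo at
  $N = 25$.
* Ties in the profit-maximising volume break toward the smaller volume;
  the curve grid is strictly increasing so `which.max` implements that.
* The default analysis window is rounds 1–51, the span all four emulated
  sessions share; every metric takes an explicit window.
* The session comparison tests delegate to `stats::wilcox.test` (normal
  approximation, two-sided) with optional Bonferroni correction; the
  package adds only the observation extraction and pooling by arm.
* Serialization: JSON is canonical (nested rounds); the CSV event table is
  equivalent and round-trips through the same validator. Outcomes are
  recomputed on read rather than trusted from disk.

Problem sizes used by the shipped tests and scripts — full 0–192 volume
grids with 100-network ensembles, $10^5$-draw Monte Carlo cross-checks,
sessions of 51–86 rounds — were chosen so the whole suite completes in a
few minutes on one core while leaving every stochastic check at least three
standard errors of slack.

# Known limitations

* The suggestion graph constructor is specific to $5 \times 5$; the index
  rules do not generalise to other $N$, and no alternative suggestion
  topologies (e.g. the star network that maximises group profit at the cost
  of equality) are implemented.
* The expected-profit ensemble conditions only on total volume; degree
  heterogeneity, clustering or community structure in real inquiry networks
  are outside the model, exactly as in the published curves.
* The generator does not model within-session learning, free-riding
  strategies, or belief formation; equilibrium analysis of the game is
  documentation only.
* `load_deposited()` maps flat event tables; if the archived sessions use a
  different layout (e.g. wide per-round files), the schema map will need a
  small adapter, which is why ingestion is isolated behind it.
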