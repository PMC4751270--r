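---
title: "A trust-dynamics cognitive model of iterated 2x2 games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trust-dynamics cognitive model of iterated 2x2 games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustgames)
```

## The modeling problem

When people play iterated 2x2 games of strategic interaction they do
more than react to the last round: they learn the opponent's move
sequences, they learn which of their own actions pay off, and they
develop *trust* that changes what "paying off" even means to them.
`trustgames` implements a learning agent built on three general
mechanisms -- instance-based sequence prediction, reinforcement-style
utility learning, and a two-accumulator trust mechanism that switches
the agent's reward function -- and the simulation experiment in which
such an agent plays two 50-round games against scripted confederate
agents under 16 conditions (game order x confederate strategy x
confederate trustworthiness).

Two games are supported, each with moves `A` (defect) and `B`
(cooperate):

* **Prisoner's Dilemma (PD)**: (B,B) pays (1,1); (A,A) pays (-1,-1);
  (A,B) pays (4,-4).  The iterated optimum is repeated mutual
  cooperation, 1 point per round.
* **Chicken Game (CG)**: (B,B) pays (1,1); (A,A) pays (-4,-4); (A,B)
  pays (4,-1).  The iterated optimum is asymmetric alternation of the
  unilateral roles, 1.5 points per round on average.

The games share a surface feature (mutual cooperation pays (1,1) in
both) and a deeper one: in both, the optimal stream requires the
players to trust each other and coordinate.  Because the same agent
carries its memory, utilities and trust accumulators from the first
game into the second, the package can be used to study transfer of
learning between the games.

## Confederate agents

The opponent is a scripted confederate implementing one of three
strategy rules plus a trustworthiness manipulation:

* **T4T** (Tit-for-Tat) copies the other player's previous move.
* **Pavlov** (win-stay/lose-shift) repeats its own previous move iff
  its previous payoff was positive.
* **PT4T** (Pavlov-Tit-for-Tat) behaves as T4T except after its own
  winning defection, where it stays with defection (the Pavlov
  component); equivalently it cooperates only after mutual
  cooperation.  PT4T therefore exploits unilateral cooperation and
  alternation can never be established against it.

All strategies open with cooperation.  Trustworthiness is manipulated
through *forced rounds* fixed per script: a high-trustworthiness (HT)
agent cooperates unconditionally on the forced rounds, a
low-trustworthiness (LT) agent defects on them.  T4T scripts force 5
of 50 rounds (10%), PT4T scripts 17 (35%) -- the stronger dose is
needed because PT4T is inherently less trustworthy.  Ten script
versions per strategy x trustworthiness cell are generated with
forced-round positions sampled uniformly without replacement, and each
model run draws one version per game, mirroring a between-subjects
assignment.

## The cognitive model

Each round the model runs the pipeline: predict the opponent's move,
choose its own move by utility, observe the outcome, encode it in
memory, update the trust accumulators, select a reward function, and
reinforce the chosen action.

**Sequence prediction.** The model stores instances
`(own previous move, other's previous move, other's current move)` in
a declarative memory with one clock tick per round (at most 2x2x2 = 8
distinct instances, each with its presentation times).  Retrieval uses
both previous moves as an exact-match cue and returns the
continuation carried by the most *active* matching instance, where
base-level activation of an instance presented at ticks $t_j$ is

$$a = \ln \sum_j (t - t_j)^{-d} + \epsilon,
  \qquad \epsilon \sim \mathrm{Logistic}(0, s_{act}),$$

so both frequency and recency of past situations drive the
prediction.  There is no partial matching or blending; with no
matching instance (or below the retrieval threshold $\tau$) the
prediction is `unknown`.

**Choice and learning.** Utilities are indexed by the context
(predicted other move, own previous move, other's previous move) and
the candidate action.  The model picks the action with the highest
utility after logistic noise of scale $s_{util}$ (exact ties break
uniformly), and afterwards updates only the taken action's utility by
the difference rule $U \leftarrow U + \alpha (r - U)$.  The reward
$r$ is *not* fixed: it is computed by whichever reward function the
trust mechanism currently selects.

**The trust mechanism.** Two accumulators start at zero at the start
of the first game and persist across both games.  *Trust* tracks the
opponent's demonstrated trustworthiness: it rises whenever the
opponent cooperates (mutual cooperation, or the model's own
unilateral defection) and falls whenever the opponent defects.
*Trust-invest* tracks the necessity of building trust: it rises under
mutual defection and falls when the model's own cooperation is
exploited.  Their signs select the reward function:

| trust | invest | reward function | learned style |
|---|---|---|---|
| > 0 | any | $P_1 + P_2 - P_2'$ | maximize joint payoff (minus the other's previous payoff) |
| <= 0 | > 0 | $P_2$ | invest in the other player |
| <= 0 | <= 0 | $P_1 - P_2$ | selfish competition |

where $P_1, P_2$ are this round's own/other payoffs and $P_2'$ is the
other's previous payoff (0 before the first round; carried across the
between-game break, which is treated as a zero-duration event).
Selection is evaluated after the accumulators absorb the just-finished
round, and the selected function rewards that round's action.

Model variants used for comparison: the *reactive* model keeps only
the trust accumulator (joint reward when positive, selfish otherwise),
and five *fixed* variants disable the mechanism entirely and reinforce
with one of $P_1$, $P_2$, $P_1+P_2$, $P_1-P_2$, $P_1+P_2-P_2'$
throughout.

## Design choices in the accumulator dynamics

The directional update rules above leave the accumulator *dynamics*
open, and three choices here are the package's own:

* **Bounded trust** (`trust_bound = 2`).  An unbounded counter
  saturates psychologically implausibly: after 30 rounds of mutual
  cooperation it would take 30 rounds of evidence to change one's
  mind, and a handful of scripted defections could never flip the
  regime.  Bounding trust at a small magnitude makes it a responsive
  sign-detector with modest hysteresis, consistent with evidence that
  trust is most volatile where experience is thin.
* **Costly failed investment** (`invest_loss = 25`,
  `invest_floor = -50`, `invest_bound = 2`).  A unit-symmetric invest
  accumulator re-triggers an investment attempt every two or three
  rounds of mutual defection, producing far more unilateral
  cooperation than a learner should show against a consistently
  exploitative opponent.  Charging a failed investment (own
  cooperation met by defection) many steps silences the proactive
  channel for a long stretch before another attempt, yielding
  occasional, spaced repair attempts instead of a pump.
* **Cooperative opening prior** (`coop_prior = 1`).  The utility of
  cooperating in the opening (no-history) context starts at 1 rather
  than 0, so a fresh agent leans cooperative on round 1, as human
  players overwhelmingly do; afterwards the entry is updated by
  rewards like any other.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `d` | 0.5 | per ln-tick | base-level decay of instance activation |
| `s_act` | 0.5 | logistic scale | retrieval noise |
| `tau` | -10 | activation | retrieval threshold (effectively off) |
| `alpha` | 0.3 | (0, 1] | utility learning rate |
| `s_util` | 0.3 | logistic scale | choice noise |
| `coop_prior` | 1 | utility points | opening cooperation prior |
| `step_trust`, `step_invest` | 1 | accumulator steps | per-event increments |
| `trust_bound` | 2 | steps | trust saturation |
| `invest_bound` / `invest_floor` | 2 / -50 | steps | invest saturation |
| `invest_loss` | 25 | steps | cost of a failed investment |

The defaults were calibrated once, jointly, against the model's
published headline predictions for the Tit-for-Tat conditions (mean
alternation in first-game Chicken under HT, mean mutual cooperation in
first-game PD under HT, and mean alternation in second-game Chicken
under LT), within conventional ranges for the memory and learning
parameters, and then frozen.  Two of those three quantities fall
within two standard errors of the published means under the default
seed; second-game LT alternation remains a few points too high -- the
residual comes from occasional noise-driven repair attempts whose
Tit-for-Tat echo registers as alternation, and in our exploration it
could not be removed without also destroying the high-trustworthiness
quantities or deadening the invest mechanism altogether (see
Limitations).

## The experiment harness

`run_experiment()` crosses 4 game orders x 2 strategies x 2
trustworthiness levels (the shipped `condition_table()`), runs 50
simulated participants per condition, each playing two 50-round games
with one of 10 agent script versions per game, with all model state
persisting across the games.  Seeds are derived deterministically from
one master seed, and the agent-version assignment stream is split from
the model-noise stream so that variant sweeps (trust vs reactive vs
fixed) see identical opponents -- model comparisons are paired.  A
`strategy_switch` flag makes the confederate swap T4T and PT4T at the
second game, the probe that separates the full trust model from the
reactive one most clearly.

## Analysis metrics

* `proportion_profile()`: per-round proportions, across runs, of the
  five outcome classes -- mutual cooperation (CC), unilateral
  cooperation (CD), unilateral defection (DC), mutual defection (DD),
  and alternation (ALT: opposite moves now and on the previous round,
  with both players switching).  ALT takes precedence over CD/DC so
  the five classes partition each round; round 1 of each game can
  never be ALT, and classification does not look across the
  between-game boundary.
* `repetition_propensity()`: per round, the probability of repeating
  one's own previous move conditional on the previous move-pair
  outcome ("A after AA"), with cells left `NA` where the conditioning
  outcome did not occur; `propensity_difference()` reports
  human-minus-model difference scores (positive = model
  under-predicts repetition).
* `fit_statistics()`: Pearson r and RMSD between two profile sets,
  flattened over rounds x classes (per condition, or pooled).
* `transfer_test()`: a paired t-test over the 50 round-level
  proportion pairs of a game played first vs second (df = 49;
  positive t means the proportion dropped when the game came second).
* `steiger_z()`: the dependent-correlation Z test (shared variable,
  Fisher z transform with the pooled-estimate covariance term), used
  to compare two models' correlations with the same observed data.
* `smooth_series()`: a loess smoother (span 0.2 by default) used for
  plotting round-by-round series only, never in statistics.

## Synthetic round logs

`synthetic_round_log()` draws each round's move pair independently
from a specified mix over the four move-pair outcomes.  It emulates
exactly one thing: a round log with a known generating outcome
profile, which makes it the ground truth for testing the metrics
layer (recovered proportions equal the mix; recovered propensities
equal constructed fractions).  It deliberately does not emulate
sequential dependence, learning, or trust dynamics -- so passing
metric tests on synthetic logs says nothing about model validity on
real play, only that the measurement layer measures correctly.

## Numerical and procedural choices

* One clock tick per round, continuous across both games; the
  between-game break is a zero-duration event for memory decay and
  the $P_2'$ term.
* Retrieval cues must match exactly; `unknown` predictions form their
  own utility contexts.
* Exact utility ties break uniformly at random; with the default
  noise scales ties effectively never occur after round 1.
* The agent reacts to actually played moves (including its own forced
  moves); its strategy state is never counterfactual.
* Accumulator updates use the raw move pair of the round, not the
  5-way metrics classification (an alternation round updates trust
  through its constituent unilateral outcome).
* Paired transfer tests use df = pairs - 1 = 49 for 50-round series;
  degenerate all-equal differences return t = 0.
* Test and example problem sizes: unit tests run conditions at 2-4
  runs; the acceptance checks run the full 16 x 50 x 100 experiment,
  about 15 seconds on one CPU.

## Limitations

* The cognitive layer is a minimal instance-based learner: no
  spreading activation, no blending, no production compilation, no
  latency model.
* The accumulator dynamics (bounds, investment cost, opening prior)
  are this package's calibrated design; other dynamics consistent
  with the same directional rules exist, and the residual
  over-prediction of second-game low-trustworthiness alternation
  documented above is the visible seam.
* Human round logs are not shipped; predictive-validity comparisons
  against real data require ingesting logs through
  `read_round_log()`'s CSV schema, and the package validates the
  comparison pipeline on synthetic logs only.
* Confederates are scripted and non-adaptive by design; none of this
  licenses conclusions about human-human play.
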