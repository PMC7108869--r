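---
title: "Task-set learning by temporal chunking: model, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-set learning by temporal chunking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunknet)
```

## The task

A subject (human or simulated agent) learns by trial and error which of
`nA = 4` actions is correct for each of `nS = 3` visual stimuli. The full
stimulus-to-action map — the *task-set* — is an injective function (no two
stimuli share an action) that stays fixed for an *episode* of 36–54 trials
and then switches without warning. Feedback is binary and unreliable:
on 10% of trials (exact count per session, positions shuffled) the reward
is inverted, so a single unrewarded trial is ambiguous between an error, an
uncued switch, and noise. A *session* is 25 episodes. In the *recurrent*
session three fixed task-sets reoccur; in the *open-ended* session each
episode brings a novel map. Consecutive episodes never share a single
stimulus-action pair.

Two combinatorial facts shape the generator. First, pairwise-disjoint
injective task-sets form a Latin-rectangle structure, so a recurrent pool of
`k` sets exists iff `k <= nA`. Second, only `4 * 3 * 2 = 24` injective maps
exist at all, so a 25-episode open-ended session cannot be entirely
repeat-free; `generate_session()` avoids exact repeats while an admissible
novel map remains and afterwards enforces only the non-overlap rule.

## The model

Two subnetworks interact. All populations are binary (active/inactive
within a trial); the model's entire memory is two weight matrices.

**Associative network (AN).** One plastic weight `J_AN[s, a]` in `[0, 1]`
per stimulus-action synapse. Actions are drawn from a soft, noisy
winner-take-all rule

\[
P(a \mid s) \;=\; \frac{\epsilon}{n_A} \;+\; (1-\epsilon)\,
\frac{e^{\beta J_{sa}}}{\sum_k e^{\beta J_{sk}}},
\]

with inverse decision noise `beta` and lapse probability `epsilon`. After
feedback `r`, only the presented stimulus's row is updated at a single rate
`alpha`: on reward, the chosen synapse moves toward 1 and the row's other
synapses toward 0; on null reward the roles are exactly swapped (including
the somewhat counter-intuitive potentiation of non-chosen synapses, which
is implemented exactly as the model defines it). The soft bounds keep every
weight in `[0, 1]` with saturation and forgetting.

**Task-set network (TN).** One population per stimulus-action conjunction,
fully connected with directed weights `J_TN in [0, 1]`, zero diagonal. The
realized conjunction of a trial activates its population; any population
receiving a synapse of weight `>= g_I` from an active one activates in
turn, iterated to closure — directed-graph reachability over the
thresholded matrix. `g_I` stands in for uniform recurrent inhibition.
Plasticity is Hebbian in time: the synapse from the previous trial's
conjunction to the current one is potentiated at rate `Q_P`, and the
current conjunction's outgoing synapses decay by factor `(1 - Q_M)`
(pre-activated depression). Under stationary pair statistics where the
source pair occurs with probability `p` per trial and the source-target
transition with probability `p^2`, the expected drift vanishes at

\[
J^* \;=\; \frac{p\,Q_P}{p\,Q_P + Q_M},
\]

an increasing function of temporal contiguity. Chunking — co-activation of
a whole task-set from any one of its pairs — requires `J* > g_I`, which
ties the usable `Q_P / Q_M` ratio to the threshold. With `p = 1/3`,
`Q_P = 0.17` and `Q_M = Q_P / 10`, `J* = 10/13 ≈ 0.77 > 0.5`; the package
verifies the closed form against a stochastic micro-simulation.

**Inference signal.** If the trial was rewarded, every conjunction in the
TN's active closure feeds back into the AN:
`J_AN[k] <- J_AN[k] + J_INC * (1 - J_AN[k])`. This is the mechanism of
task-set retrieval: one confirmed association re-imposes the whole chunked
rule on the decision weights. The "without inference" model variant is the
same system with this pathway removed and is exactly equivalent to
`J_INC = 0` (a tested property).

**Trial order.** Within a trial: (1) action selection, (2) feedback,
(3) AN plasticity, (4) TN closure from the realized conjunction using
start-of-trial TN weights (activation is treated as instantaneous),
(5) TN plasticity, (6) inference if rewarded. The closure precedes TN
plasticity (activity drives plasticity), and the inference applied at the
end of trial `t` is what biases the decision at `t + 1`. The
previous-conjunction memory used for potentiation spans episode boundaries
(switches are uncued) but resets at session start and after a lapse — a
lapse has no realized conjunction, and potentiation is defined for
consecutively activated conjunctions.

## Parameters

| parameter | meaning | default | range |
|---|---|---|---|
| `alpha`   | AN learning rate | fit / 0.35 | `[0, 1]` |
| `beta`    | inverse decision noise (`1/beta` is reported as noise) | fit / 7 | `[0, 50]` for fitting |
| `epsilon` | lapse / undirected exploration | fit / 0.05 | `[0, 1]` |
| `qp`      | TN potentiation rate (the TN's only free parameter) | fit / 0.17 | `[0, 1]` |
| `j_inc`   | inference strength | fit / 0.70 (recurrent), 0.16 (open-ended) | `[0, 1]` |
| `qm`      | TN depression rate | fixed `qp / 10` | — |
| `g_i`     | activation threshold | fixed 0.5 | — |

`qm` and `g_i` are fixed by convention to remove a redundancy: only the
ratio `qp/qm` relative to `g_i` matters for whether chunking occurs. The
with-inference model has 5 free parameters, the without-inference model 3.

## Which conjunctions learn? (a deliberately narrow rule)

The plasticity equations are written in terms of the *realized*
conjunctions of trials `t` and `t + 1`, but co-activated populations also
have activity 1, so an outer-product reading — potentiate all active-at-t
to all active-at-t+1 synapses, depress every active population's outgoing
row — is textually defensible. The package implements the narrow reading:
potentiation only between the two directly driven conjunctions, depression
only of the driven conjunction's outgoing row. Two reasons. First, the
closed-form equilibrium above (and its printed consequence `J* ≈ 0.77`) is
the fixed point of the narrow micro-rule. Second, in simulation the
outer-product variant chunks the exploratory noise that follows every
episode switch far faster (whole clusters get wired to whatever follows
them), and with it the inference signal becomes harmful even at slow TN
rates — eliminating the speed–accuracy trade-off that is the model's
central behavioral regime. The narrow rule reproduces that regime: the
inference advantage is positive for `qp < alpha` (e.g. 0.17 vs 0.4) and
reverses for `qp >= alpha`, which the test suite checks over paired
simulations.

## What "performance" means for the trade-off

Retrieval acts in a specific place: the trials immediately after an
episode's first correct response, when one confirmed association can
restore the rest of the rule. Averaged over whole episodes the effect is
diluted (and slightly offset by the inference pinning weights at
`j_inc < 1` during the plateau). The package therefore measures the
trade-off the way the model's own sweep defines performance: the mean
model probability of the correct action over the five trials following
each episode's first correct response, restricted to the last third of the
session. `scripts/acceptance.R` recomputes both this quantity and its
sign reversal at fast TN rates.

## The idealized, fully chunked network

`tn_idealized()` builds the hand-wired TN in which each task-set's three
conjunctions are mutually connected at 0.7 (above threshold) and everything
else is silent. Runs with it freeze TN plasticity: the idealized encoding
is a postulate, not something being learned, and pre-activated depression
would otherwise erode the fixed clusters over a long session. With
`j_inc = 1` this configuration makes retrieval exact: on the trial after an
episode's first *rewarded* correct response, all three AN weights of the
current task-set equal 1.0 — exactly, because the package computes
soft-bound updates in the convex-combination form
`J <- rate + (1 - rate) * J`, which is exact at `rate = 1` where the
algebraically identical `J + rate * (1 - J)` is not in floating point.

Two ceiling effects deliberately *absent* from this package's claims: even
the idealized retriever is not at 100% on newly seen stimuli or right
after the jump, because a stimulus unseen since the switch still carries
the previous task-set's near-1 AN weight, and the winner-take-all rule
then faces two strong candidates (probability near 1/2 at `beta = 7`).
The test suite asserts the directional gaps (retriever far above the
AN-only control) rather than a ceiling. Likewise, a misleading null
feedback necessarily depresses the presented stimulus's row one trial
before the reward-gated inference can repair it, so the post-feedback dip
is confined to the next same-stimulus trial and vanishes on cross-stimulus
trials — the robustness checks compare drops between the two model
variants and verify the cross-stimulus flatness, not a literal zero dip.

## Fitting

Subject-level maximum likelihood under teacher forcing: the model's state
evolves under the subject's recorded actions and rewards, and the
likelihood of each recorded action comes from the winner-take-all rule at
the evolving weights. Lapse trials (no action) contribute nothing and
trigger no updates. Optimization is a coarse factorial grid (3 values per
free parameter) whose best points seed bounded `L-BFGS-B` runs; the result
is deterministic given grid, bounds and data, with ties broken by lower
negative log-likelihood then grid order. Sessions are fitted separately by
default; a joint fit over a list of sessions (fresh state per session,
summed likelihood) is available and can only do worse in total
log-likelihood — a nesting property the tests check.

Model comparison uses the halved-deviance conventions
`BIC = -logL + (k/2) ln n` and `AIC = -logL + k` with `n` the number of
non-lapse trials — the negative of the Laplace-approximation evidence
rather than the more common `-2 logL` scaling. Only differences matter for
selection; on this scale the with/without BIC difference equals the
half-deviance difference plus `ln n` for the two extra parameters. The AIC
scaling is chosen for consistency with this convention; conclusions are
treated as scale-invariant (selection only).

The trial loop exists twice on purpose: a reference R path assembled from
the exported per-trial operations, and a compiled engine used by default
for simulation and likelihoods. Both consume one uniform variate per
simulated trial in the same order, so seed-matched runs are bitwise
comparable, which the tests exploit (`engine = "R"` vs `engine = "cpp"`).
The engines encode the TN active set as a bitmask and therefore support up
to 31 conjunction populations — far above the task's 12.

## Synthetic cohorts

The original participants' data are not redistributable, so
`generate_cohort()` emulates them: per-subject parameters drawn from
normals centered on the fitted group means (`alpha` 0.35, `qp` 0.17,
`j_inc` 0.70 recurrent / 0.16 open-ended) with spreads on the scale of the
reported between-subject variability, truncated to the parameter ranges;
one fresh session per subject; optional lapses injected by deleting
actions after simulation (the agent's internal updates for those trials
are not rewound — a simulated subject that failed to respond, not one that
never processed the trial). What the cohorts do **not** emulate: reaction
times (carried as a passthrough column only), within-session
non-stationarities such as fatigue, any stimulus-schedule balancing the
original experiment may have used (stimuli are i.i.d. uniform here), and
the debriefing-based exploiting/exploring distinction. Passing
parameter-recovery and model-selection checks on these cohorts shows the
estimator works at the experiment's size and noise level; it does not by
itself validate the model against human behavior.

## Problem sizes and numerical choices

The test suite runs the mechanism checks at moderate scale chosen for
statistical resolution: 1,000 random states/graphs for the exact
numerical equivalences, 1,000 episodes for exact idealized retrieval,
50,000 micro-updates for the chunking equilibrium (tolerance ±0.05),
200 paired sessions per TN rate for the trade-off, ≥5,000 events for the
misleading-feedback comparison, and 20 synthetic subjects for recovery
(median absolute error ≤0.1 on `alpha`, `qp`, `j_inc`) and BIC selection
(≥90%). Probabilities are computed with log-sum-exp stabilization;
`beta` is capped at 50 during fitting, far above any plausible estimate.

## Known limitations

- The AN-only plateau under 10% misleading feedback sits near 0.86 (not
  higher): the null-reward branch potentiates all non-chosen synapses, so
  each misleading trial meaningfully flattens the row. This is a property
  of the printed update rules, verified against an independent
  reimplementation.
- Open-ended sessions longer than 24 episodes must repeat a mapping
  (finite map space); novelty is enforced only while feasible.
- The fitted `beta` and `epsilon` partially trade off in short sessions;
  recovery guarantees target `alpha`, `qp`, `j_inc`.
- All analyses assume the behavioral CSV's reward column already encodes
  the (possibly inverted) feedback actually delivered.
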