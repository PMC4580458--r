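---
title: "Inferring dyadic smile goals by inverse optimal control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dyadic smile goals by inverse optimal control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilegames)
```

`smilegames` treats a smiling dyad as a control problem: one member (the
*agent*) acts on the other (the *plant*) by starting and stopping its own
smile, and we ask which dyadic end state those actions are best explained
by. This vignette is the package's own account of the method — the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data tests do and do not establish.

## Data model and gaze gating

Input data are onset/offset events per actor and behaviour
(`read_event_csv()`), binned to a fixed grid by `bin_events()`. The default
bin width is 1 s, matching the second-scale at which smile timing is usually
analysed; a bin scores 1 when the behaviour covers at least half of it,
computed by exact interval intersection (the threshold is symmetric and
configurable). Bins are 0-based and episodes half-open.

Analysis episodes are maximal runs of gaze-at-partner (`extract_episodes()`,
`min_len_bins = 2`). Gating ensures the agent could actually see the
partner's smiles; we apply it to both the infant-as-agent and
mother-as-agent analyses by default — the information argument is one-sided,
but gated data are the conservative common denominator — with `gaze_gate =
FALSE` available for the mother side. Runs shorter than 2 bins contain no
usable transition context, hence the default; it is a package choice, not an
empirical fact. Elapsed-time counters reset at every episode start, so
nothing is assumed about behaviour during look-aways. Episodes from all of a
dyad's sessions are pooled, giving one fit and one posterior per dyad.

## The plant: a semi-Markov toggle model

`fit_hazard()` estimates the probability that the modelled partner *toggles*
its smile state in the next bin, in cells indexed by its own state
`s_self`, the other member's state `s_other`, and the elapsed time `tau`
(bins since the partner's own last toggle, capped at `K - 1`). The cap
pools hazards beyond `K = 30` s, where data are sparse. Cells are
Laplace-smoothed, `h = (toggles + alpha) / (exposures + 2 alpha)` with
`alpha = 1`, so every trajectory has positive likelihood and planning never
divides by zero. This model class expresses both regularities the analysis
relies on: responsivity (onset hazard higher while the other smiles) and
duration-dependent cessation (offset hazard rising in `tau` while smiling
alone). It deliberately excludes covariates beyond the joint state and
`tau`.

## The agent: planning and the four goals

`build_mdp()` assembles the agent's decision problem against a fitted
plant. States are `(a, p, tau_a, tau_p)`; actions are keep/toggle; the
agent's own elapsed-time cap is `K_a = 10` (the agent's `tau` matters only
through the partner's perception, so a shorter memory suffices; both caps
are configurable). The causal ordering gives one bin of reaction latency:
the partner's toggle hazard is evaluated at the agent's *pre-action* state,
so an action is seen by the partner from the following bin. Reward 1 is
collected whenever the post-transition configuration matches the goal —
one of `mutual`, `mother_only`, `infant_only`, `neither`, mapped onto
(agent, partner) targets by the agent's role.

The objective is infinite-horizon discounted value with `gamma = 0.98` per
second. "Maximise time in a configuration" would canonically be an
average-reward criterion; discounted value iteration with `gamma` near 1
approximates it while remaining numerically simple, and `gamma` is exposed
and reported. `value_iteration()` iterates the Bellman backup to a sup-norm
residual below `1e-9` (ties break toward `keep`); with 1200 states and two
successor states per action this takes about a thousand sweeps and well
under a second.

`wait_time_performance()` evaluates the family of fixed-wait strategies
("hold for t bins, then toggle, then act optimally") from a context state by
exact dynamic programming, normalised by `1/(1 - gamma)` so 1 means the goal
configuration every bin forever. The normalised discounted occupancy is this
package's definition of a wait time's "performance"; the canonical context
is partner smiling, agent just stopped (`a = 0, p = 1, tau_a = 0`, and
`tau_p = 0` by default since the partner's smile age at entry is not part of
the context definition).

## Goal inference

The bridge from optimal plans to observed behaviour is a Boltzmann
noisy-rationality likelihood: an agent pursuing goal g picks action u in
state s with probability proportional to `exp(beta * Q_g(s, u))`. Nothing in
the analysed behaviour identifies `beta` a priori, so the evidence for each
goal marginalises it over 16 log-spaced values on [0.1, 100] (uniform grid
prior, log-space averaging), spanning near-random to near-deterministic
acting. An epsilon-greedy alternative (`rationality_config(model =
"epsilon_greedy")`) is provided for sensitivity analysis. The goal prior is
uniform (0.25 each), so a posterior above 0.25 is evidence in favour. Per
dyad, the partner model is fitted on all of that dyad's episodes; no
held-out split is applied for the headline analysis, because the partner fit
and the action likelihood concern different members of the dyad.

## The synthetic cohort: what it does and does not show

`make_cohort()` generates dyads whose plant follows the parametric hazards
of `generator_params()` — onset 0.03/bin (×4.0 while the other smiles),
offset `min(0.02 + 0.02 tau, 0.5)` while smiling alone, 0.05 during mutual
smiling — and whose agent samples actions from `softmax(beta * Q)` of the
true optimal plan (`beta = 20`), with gaze an independent Markov chain (60%
on, 8-s mean runs), 10 sessions of 300 s per dyad, and ±20% lognormal
per-dyad jitter on all hazards (capped at 0.5, which keeps toggling
identifiable at 1-s bins). These values are the package's definition of a
realistic, responsive dyad at 1-s resolution and are not adjusted per
analysis.

Because the synthetic agent is generated *from the planner itself*, cohort
recovery tests establish internal consistency — fit, plan, likelihood and
posterior agree end to end, and gaze gating's elapsed-time resets do not
break identification — not external validity. A hand-coded reflex agent
(`agent_kind = "reflex"`) probes inference under misspecification. Known
departures from real data: facial expressions are binary with no intensity;
gaze is independent of the interaction; the synthetic agent's wait-time
distribution in the canonical context does not reproduce the short 1-s mode
characteristic of real infants (its optimal-policy waits are longer and
often right-censored); and real partners are not exactly semi-Markov.

## The simulated controller study

`run_experiment()` replays the controller-versus-adult design in software:
32 participants, four 3-minute sessions each in a Williams Latin-square
order, with the four controllers *infant* (argmax of the inferred
infant-goal policy; a `beta` flag enables stochastic acting), *replay* (the
previous participant's infant-controller trace, hence zero contingency),
*mirror* (the participant's state one bin ago; latency configurable, 1 s
default as the smallest causal delay), and *infant plus* (infant action
overwritten by the participant's current state with probability 0.5 per
second). The adult is a hazard-model plant of the same family as the mother
model with per-participant jitter — a simulated stand-in for human
participants, which is exactly what makes this a software replication rather
than a reproduction. The positivity questionnaire enters only as a proxy
scalar: mutual-smiling seconds plus Gaussian noise (sd 40 score units,
calibrated so the correlation with mutual smiling sits in the moderate
range).

## Statistics

`binom_tail()` sums the binomial pmf directly (checked against the
incomplete-beta identity at 1e-12). `rm_anova_gg()` performs the one-way
within-subject decomposition with the Greenhouse–Geisser epsilon estimated
from the double-centred condition covariance; the correction is applied
whenever k > 2 by default ("when appropriate" is otherwise under-specified),
with `gg = "mauchly"` to gate it on Mauchly's test and `gg = "never"` for
the uncorrected F. Note the GG-corrected test is conservative when
sphericity actually holds; only the uncorrected p-values are uniform under a
spherical null. Effect size defaults to *partial* eta squared
(`SS_effect / (SS_effect + SS_error)`), the usual within-subjects report;
classical eta squared is also returned. Degenerate inputs are defined
explicitly: identical condition profiles give F = 0, p = 1; fully constant
data are an error; zero-variance nonzero paired differences are an error
while identical paired samples give t = 0, p = 1.

## Numerical choices and limitations

* Value-iteration tolerance 1e-9 (sup-norm residual); action ties break to
  `keep`; all elapsed-time counters saturate at their caps.
* Evidence is computed in log-space (`log-mean-exp`) so small posteriors
  underflow gracefully; posteriors on long, strongly goal-directed records
  saturate at 1 to machine precision, which makes across-goal ANOVAs of
  saturated synthetic posteriors degenerate (infinite F) — a property of the
  synthetic regime, not of the method.
* Wait-time curves are exact expectations by dynamic programming; Monte-Carlo
  rollouts appear only as test oracles.
* Problem sizes used in the shipped tests (13 dyads × 10 × 300-s sessions;
  100 replicate experiments of 32 participants; 100,000 rollouts for the
  wait-curve check) were chosen to make the statistical checks decisive at
  desktop scale.
* Out of scope: continuous-time hazards, facial-expression intensity or
  recognition, partially observed states, dynamic goals (e.g. *changing* the
  partner's state), and robot hardware.
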