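---
title: "Modelling choice seeking in a two-stage task: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice seeking in a two-stage task: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicerl)
```

## The task and what the package models

`choicerl` models behavior in a two-stage decision task probing the
intrinsic value of choice. On each trial a subject first faces a decision
between two first-stage options: *free*, which leads to a self-determined
choice between two fractal targets, and *forced*, where the computer
mandates the terminal action. Extrinsic rewards (0/1) follow terminal
actions only. Each block fixes the reward probabilities and uses fresh
fractals; a training phase (experimenter-scheduled first-stage cues,
equal numbers of free- and forced-type trials) precedes a test phase in
which the subject genuinely chooses at stage 1.

Three task variants are implemented in `build_config()`:

* **Graded probability** (`exp1a`, `exp1b`): the maximal reward
  probability P is matched between free and forced options and varies
  across blocks (0.5/0.75/1, or 0.5/0.67/0.83/1 in the four-block
  version); the non-best free target pays 1 − P. 48 training trials per
  option and 48 test trials per block, except 24 training per option in
  the deterministic block, where learning saturates quickly.
* **Relative value** (`exp2`): free targets fixed at 0.75/0.25 while the
  forced target pays 0.75, 0.85 or 0.95; 40/40/40 trials. The parity
  block is always first, the rest are permuted.
* **Incoherence** (`exp3`): every target pays 0.75 and, with block-wise
  probability 0, 0.15 or 0.3, the displayed second-stage target is
  swapped relative to the emitted action. The forced option here leads to
  a two-action terminal state (the computer picks one of two fractals),
  giving a 7-state task graph instead of the 6-state graph of the other
  variants. The fully coherent block is always first.

Interleaving of free- and forced-type training trials is random under the
equal-count constraint; screen-side randomization is not modelled
(actions are abstract `a1`/`a2`) because no analysis in scope depends on
it.

## The agent family

Agents maintain a table of state-action values Q(s, a) updated at both
stages of each trial with the prediction error

$$\delta_t = r_{t+1} + Z(s_{t+1}, a_{t+1}) - Q(s_t, a_t), \qquad
Q(s_t, a_t) \leftarrow Q(s_t, a_t) + \alpha\,\delta_t .$$

The future-value target Z distinguishes three learners: one-step SARSA
(value of the action taken next), Q-learning (best next value), and a
*β-pessimistic* learner using
$\beta \max_{a'} Q + (1-\beta) \min_{a'} Q$, which interpolates from
total risk aversion (β = 0) to Q-learning (β = 1). Optionally a
*free-choice bonus* ρ is added to every outcome obtained through the free
option — rewarded or not, in training and test — so the inflated reward
propagates into later value updates; this is the mechanism that lets
value learning itself overvalue self-determined outcomes. Choices follow
a softmax with per-stage temperatures τ₁, τ₂, optionally augmented by a
stickiness increment κ for repeating the previous first-stage choice, or
by a *static bias* b on the free option that shifts choice utilities
without ever entering value updates (the supplementary alternative to the
bonus).

Crossing 3 targets × bonus on/off × 1–2 learning rates × 1–2
temperatures × stickiness on/off gives the 48-member family of
`enumerate_family()`; the static-bias variant is deliberately kept
outside it and compared to the bonus model separately
(`compare_bonus_vs_bias()`). Each spec is fit at both value-table
initializations (0 and 0.5), treated as a hyperparameter selected per
subject.

Design choices where the update scheme was genuinely open:

* No discounting and no eligibility trace: terminal rewards reach the
  first stage only through the learned second-stage values.
* The stage-1 backup uses the second-stage values *before* the trial's
  outcome update (the one-step online convention); the stage-2 update
  then applies the effective reward with zero future value.
* On incoherent trials the stage-2 update credits the *emitted* action
  with the reward as delivered; the subject controls only the action, and
  the displayed target is treated as feedback noise.
* First-stage cue values are shared across blocks (the cues are reused,
  while fractals are fresh per block); `share_stage1 = FALSE` switches to
  per-block first-stage values.
* The stickiness indicator resets at the first test trial of each block;
  training has no first-stage choices to repeat.

## Likelihood, priors and fitting

The likelihood replays a subject's full log — training and test, all
blocks, chronologically — through the update equations, summing log
softmax probabilities over the modeled decisions: second-stage choices on
free-type trials (both phases) and first-stage choices (test). Forced key
presses contribute probability 1 but still drive updates, and training
values carry into test. The replay is implemented in C++ because MAP
fitting evaluates it thousands of times per subject; an independent
straight-line R implementation is kept in the test suite and must agree
to 10⁻¹².

Estimation is maximum a posteriori with independent priors
α ~ Beta(1.1, 1.1), 1/τ ~ Gamma(shape 1.2, scale 5), β ~ Beta(1.1, 1.1),
ρ, κ, b ~ N(0, 1), optimized by L-BFGS-B on the inverse-temperature
scale with α, β ∈ [0, 1] and 1/τ ≥ 0, from 10 starts drawn from the
priors; the best converged restart wins. Box bounds are kept 10⁻⁶ inside
the Beta support because its log density diverges at the edges.
Unconverged restarts are kept only as a warned fallback when nothing
converges. Logs with zero modeled decisions are rejected rather than
fit.

Model comparison uses BIC Schwarz weights,
$w_i = \exp(-\Delta_i/2) / \sum_k \exp(-\Delta_k/2)$ with
$\Delta_i = BIC_i - \min BIC$, computed over the pooled 48 × 2
(spec × initialization) fits per subject; the maximal-weight entry is
selected, with ties broken toward fewer free parameters and then
lexicographic label. BIC plugs in the log-likelihood at the MAP estimate
with n = the number of modeled decisions — each decision is one
likelihood term, so it is the natural sample size for the penalty. A
β-pessimistic fit that collapses to β = 1 reproduces Q-learning exactly
and is then penalized for its extra parameter, as intended.

## The synthetic cohorts

The generator (`simulate_subject()`, `simulate_cohort()`) produces
complete per-subject logs under any agent in the family; all randomness
derives from the master seed, sub-seeds are drawn per subject from a
seeded stream, and block order is re-permuted per subject (as the
published designs randomize block order across subjects). Cohort
parameters are either fixed or drawn from the fitting priors, with
inverse temperatures capped at the 99th prior percentile — beyond that
choices are near-deterministic and carry almost no gradient for the
remaining parameters.

Four heuristic *strategy agents* cover the candidate second-stage
policies on the incoherence task. On each free trial they repeat or
switch their previous free-trial action according to a rule applied with
probability `adherence` (uniform otherwise): stay iff rewarded
(reward-based), stay iff coherent (swap-avoidance), stay iff
rewarded-and-coherent or unrewarded-and-incoherent (model-based), and
outcome-sensitive only on coherent trials with unconditional repetition
after incoherent ones (control-maintenance). The conditioning trial is
the most recent free trial; intervening forced trials change nothing but
recency. Their first-stage free-choice probability is a fixed parameter
(default 0.69, the level observed in the fully coherent block of the
incoherence experiment) because the strategies only specify second-stage
behavior. The exact adherence levels behind real subjects are unknown;
the agents are parameterized rather than matched to any figure.

What the generator does *not* emulate: reaction times, early-press
repeats, screen-side effects, drifting attention or satiety, and any
within-subject heterogeneity beyond the fitted parameters. Passing
recovery tests therefore demonstrates internal consistency of the
pipeline — that the fitting machinery identifies the generating process
at realistic trial counts — not that human data satisfy the model.

## Validation choices and problem sizes

Recovery analyses default to the graded-probability schedule, whose
trial counts are the largest and identifiability the best. Parameter
recovery uses 50 prior-drawn subjects fit with the generating
specification (10 restarts); rank correlations above 0.6 for the
second-stage learning rate and the bonus are the reference level of
adequacy. Model recovery runs at the family level — target type × bonus,
four families, 25 subjects each — rather than the full 48 × 48
confusion, which is computationally disproportionate and blurs the
scientifically relevant distinction. Generating draws fix the
family-defining parameters at representative values (β = 0.3 for
pessimistic generators, ρ = 0.5 for bonus generators; 0.5 is the
reward-scale magnitude used throughout the worked examples): a "bonus"
generator with ρ ≈ 0 is generatively identical to its no-bonus
counterpart and would make the confusion matrix measure prior mass near
zero rather than discriminability. β near 1 generators are *correctly*
confusable with Q-learning; that confusion is expected and concentrated
there.

The directional risk-attitude contrast uses fixed-parameter cohorts of
30 subjects (α = 0.3, τ = 0.3, β = 0.2 for pessimists; α = 0.2,
τ = 0.3, ρ = 0.5 for optimists). Two numerical facts about these cohorts
are worth knowing. First, with low exploration (τ₂ ≲ 0.15) a bonus agent
can lock onto a never-rewarded target in the deterministic block — the
unrewarded target retains value ρ while the rewarded one is never
sampled — which is a real rich-get-richer property of bonus learning,
not a bug; the moderate τ used here keeps it rare. Second, a Q-learner's
first-stage free value is slightly inflated in stochastic blocks because
the max operator is applied to noisy estimates (the optimizer's-curse
bias); the optimist profile is therefore flat-with-a-dip rather than
strictly increasing, and "does not decrease" is the honest directional
statement.

## Known limitations

* The preference reversal point is a descriptive logistic interpolation
  across block-level preferences, not a smooth population model; it is
  undefined (with a diagnostic) when preferences never cross 0.5.
* Inferential statistics on behavioral summaries (mixed models, smooth
  trends, corrected pairwise tests, reaction-time models) are out of
  scope; the summaries are deterministic descriptions of a log.
* The first-stage learning rate α₁ is weakly identified at these trial
  counts (most of its influence is absorbed by the shared cue values);
  its recovery is reported but not relied upon.
* Fitting assumes the log is one subject in chronological order; the
  reader validates structure (`read_trial_log()`) but cannot detect a
  silently re-sorted file.
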