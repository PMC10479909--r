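# choicerl

Reinforcement-learning models of human *choice seeking* in a two-stage
decision task. Subjects first decide between a **free** option — a
subsequent self-determined choice between two rewarded targets — and a
**forced** option, where the computer mandates the terminal action.
People reliably "choose to choose" even when choosing pays no better,
and sometimes when it pays worse. This package provides, for researchers
in computational cognitive science, the full modelling pipeline for that
phenomenon with a synthetic-subject generator standing in for human
data:

* **Task generators** for three variants: graded reward probability
  (matched maxima from P = 0.5 to the deterministic P = 1),
  relative-value trade-off (forced pays 0.75–0.95 against fixed
  0.75/0.25 free targets), and degraded controllability (the displayed
  target is swapped with probability 0–0.3).
* **A factorial family of 48 temporal-difference agents.** Values update
  with δ = r + Z(s′, a′) − Q(s, a), Q ← Q + αδ, where the future-value
  target Z is SARSA, Q-learning, or the β-pessimistic mixture
  β·max Q + (1 − β)·min Q (β = 1 recovers Q-learning; β < 1 weights
  the worst outcome — risk attitude). A free-choice bonus ρ is added to
  every outcome obtained through the free option (decision attitude),
  choices are softmax with per-stage temperatures and optional
  stickiness κ, plus a supplementary static-bias alternative b.
* **Trial-level MAP fitting** (compiled likelihood; priors
  α, β ~ Beta(1.1, 1.1), 1/τ ~ Gamma(1.2, 5), ρ, κ, b ~ N(0, 1);
  bounded L-BFGS-B from 10 prior-drawn starts) and **BIC Schwarz-weight
  model selection** over the 48 specs × 2 value initializations.
* **Recovery pipelines** (parameter and family-level model recovery on
  simulated cohorts) and **behavioral summaries**: free-choice
  preference, conditional preference, 2×2 stay probabilities by reward ×
  coherence, reward-repetition odds ratio, and the preference reversal
  point.

## Worked example

Simulate one subject on the relative-value task from a Q-learner with a
free-choice bonus, summarize behavior, and refit:

```r
library(choicerl)

cfg   <- build_config("exp2", seed = 42)
spec  <- new_model_spec("q_learning", has_bonus = TRUE)
truth <- new_params(alpha1 = 0.3, alpha2 = 0.3, tau1 = 0.25, rho = 0.5)
log   <- simulate_subject(cfg, spec, truth, subject_id = "demo", seed = 7)

choice_preference(log)$by_block
#>   block_index mean_pref n_subjects
#> 1           1     0.925          1
#> 2           2     0.600          1
#> 3           3     0.750          1

fit <- fit_map(log, spec, cfg, n_restarts = 10, seed = 1)
fit
#> <fit_result> q+bonus+1alpha+1tau@qinit0
#>   logLik -123.51  logPost -126.84  n_obs 331  k 3  BIC 264.42
```

The agent prefers choice most where the options pay equally
(block 1, 92.5% free) and less as the forced option becomes objectively
better. The fit recovers the generating parameters (α̂ = 0.32, τ̂ = 0.27,
ρ̂ = 0.50 against 0.3/0.25/0.5) from 331 modeled decisions. Model
comparison by Schwarz weights identifies the bonus:

```r
cmp <- select_model(fit_family(log, cfg,
  specs = list(new_model_spec("q_learning"),
               new_model_spec("q_learning", has_bonus = TRUE),
               new_model_spec("beta_pessimistic", has_bonus = TRUE)),
  n_restarts = 10, seed = 1))
cmp$selected
#> [1] "q+bonus+1alpha+1tau@qinit0"   # weight 0.93; no-bonus ΔBIC = 76
```

The `analysis/` directory holds the numbered pipeline scripts
(`01_simulate_cohorts.R` … `04_recovery.R`) that generate the study
cohorts, write behavioral tables under `results/`, fit the full model
family, and run the recovery validation. The methods vignette
(`vignettes/choicerl-methods.Rmd`) documents the model equations,
priors, design decisions and known limitations.

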