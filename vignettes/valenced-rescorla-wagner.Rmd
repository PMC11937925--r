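---
title: "Valenced Rescorla–Wagner modelling of social reinforcement learning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valenced Rescorla–Wagner modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwvalence)
```

# The task and what the package models

`rwvalence` implements a complete analysis chain for a probabilistic
two-option categorization task with valenced feedback. Participants sort
two-digit numbers into arbitrary categories A or B and learn only from
probabilistic feedback: a correct response is rewarded with probability
0.85, an incorrect one with probability 0.15. The task runs in two
feedback conditions — social (point-light faces expressing happy or angry
emotion) and non-social (check marks and crosses) — presented as two
interleaved blocks per condition, each block containing six *trial cycles*
over that condition's four stimuli. One participant therefore contributes
2 × 2 × 6 × 4 = 96 choice events, and each condition spans cycles 1–12.
Even stimulus numbers belong to social blocks and odd numbers to
non-social blocks, so stimulus identity cannot carry across conditions.

Two vocabulary decisions are worth making explicit, because the task's own
counting is ambiguous. A "trial" in the task description contains four
stimulus presentations; the package calls that unit a **cycle** (1–12,
continuous across a condition's two blocks) and each single presentation
an **event**. The trial-number covariate in the behavioural model is the
cycle. Feedback for incorrect responses is not fully pinned down by the
task description, which states the contingency for correct responses
only; the package mirrors it (incorrect responses rewarded with
probability 1 − 0.85), the standard symmetric design, and exposes it as a
single configurable contingency.

# The learner

Each stimulus carries an expected reward probability for option A,
initialized at the chance expectation 0.5; option B's value is the
complement, `P_B = 1 − P_A`. On each event the model chooses by a softmax
(logistic) rule in the value difference,

P(choose A) = 1 / (1 + exp(−θ (P_A − P_B))),

then updates the *chosen* option's value from the obtained feedback
through a reward prediction error scaled by a reward sensitivity ρ and a
learning rate α:

RPE = ρ · Outcome − P_chosen,  P_chosen ← P_chosen + α · RPE.

All three quantities are *valenced*: rewarded events use (α_win, ρ_win)
and non-rewarded events (α_loss, ρ_loss), giving six free parameters per
participant × condition once the two inverse temperatures θ_win, θ_loss
are included.

Design choices the equations leave open, and how the package resolves
them:

* **Outcome coding.** Coding the outcome literally as 1/0 (reward /
  no-reward) makes the loss-domain prediction error `−P_chosen`
  regardless of ρ_loss: the parameter drops out of the likelihood and
  cannot be estimated, even though it is analysed downstream. The package
  therefore defaults to **signed coding** (reward = +1, non-reward = −1),
  under which ρ_loss scales loss outcomes and is identified. The literal
  coding is retained as an option, and `identifiability_probe()`
  demonstrates the flat ρ_loss likelihood profile it produces; the
  parameter-recovery suite shows ρ_loss recovery collapsing to zero rank
  correlation under it.
* **Which θ applies when.** The valence split of the inverse temperature
  is interpreted as reactive: the θ used on an event is selected by the
  valence of the most recent feedback in the same condition (exploration
  after losses, exploitation after wins); the first event of a condition
  uses the mean of the two. This is one of several defensible readings;
  it is fixed here and documented rather than exposed as a dial.
* **Value representation.** Values are tracked per stimulus for option A
  only with `P_B = 1 − P_A`, and only the chosen option's value is
  updated; the complementary two-option structure of the task makes a
  second free value redundant.
* **Clipping.** Under signed coding a strong negative prediction error
  can push a value below 0; updated values are clipped to [0, 1] to
  preserve their reading as probabilities. The stationary value under
  constant reward is ρ_win, which the tests verify by long simulation.
* **Numerics.** Likelihood accumulation uses a numerically stable
  log-sigmoid, exact over the whole θ ∈ [1, 50] box; the forward
  recursion is compiled (Rcpp) because fitting and recovery evaluate it
  tens of thousands of times, and an independently written plain-R
  recursion in the test suite serves as its oracle.

# Estimation

Parameters are estimated per participant × condition by penalized maximum
likelihood. α and ρ are optimized on an unconstrained *raw* scale in
[−10, 10] and mapped into (0, 1) by the logistic function; θ is optimized
directly on [1, 50] with no transformation. The objective adds an elastic
net penalty λ₁·Σ|raw| + λ₂·Σraw² with λ₁ = λ₂ = 0.01 over the four raw
α/ρ components. θ is excluded from the penalty: it is untransformed and
its box excludes zero, so shrinkage toward zero would be ill-posed —
whereas for α/ρ the penalty pulls the raw values toward 0, i.e. the
constrained values toward the neutral midpoint 0.5.

Minimization uses bounded quasi-Newton (`optim`, L-BFGS-B) from 10 random
box-uniform starts; the best converged restart is kept and every fit
records its penalized objective, unpenalized negative log-likelihood and
convergence flag. Ten restarts and the convergence tolerance are
desk-scale robustness choices, configurable through `fit_config()`.
Failures degrade to records rather than exceptions so cohort fitting
never aborts. The L1 term is non-smooth at 0; L-BFGS-B handles this in
practice at these penalty magnitudes, and the shrinkage test verifies the
monotone contraction of the raw optimum as λ grows.

# The synthetic cohort

The study's participant-level data live in an external repository, so the
package ships a generative stand-in with the statistical structure the
analyses assume; every downstream stage is exercised on it.

* **AQ scores.** The autism-spectrum-quotient short form is binary-scored
  over 33 items (range 0–33). Scores are drawn from a beta-binomial whose
  two shape parameters are solved by moment matching to the calibration
  sample's mean 9.45 and s.d. 4.88. With only two free parameters the
  third moment is implied, not matched: the emergent skewness is ≈ 0.5,
  positive and right-tailed like the empirical 0.82 but not equal to it.
  It is reported by the calibration tests, not forced.
* **Ground-truth parameters.** Raw-scale α/ρ are drawn normally around
  population locations (α_win −0.5, α_loss −1.0, ρ_win 1.0, ρ_loss 0.0;
  between-participant s.d. 0.8) and mapped through the logistic; θ is
  drawn on its natural scale (locations 7/5, s.d. 3) truncated to
  [1, 50]. Win locations sit above loss locations, matching the reported
  ordering of fitted parameters. The AQ linkage applies a slope of
  −0.08 per centred AQ point on raw ρ_win and +0.15 per point on θ_loss —
  directions from the reported effects, magnitudes chosen once to give
  detectable effects at n = 63 (population correlations ≈ 0.3–0.4), not
  to reproduce the study's odds ratios, whose AQ scaling is not fully
  determined by the text.
* **Between-condition jitter.** Each participant's parameters get a small
  independent per-condition deviation (raw s.d. 0.3; θ s.d. 1) around
  their participant-level location. Without it the two condition rows per
  participant would be identical and the beta mixed model — participant
  random intercept plus beta residual — would be degenerate on generator
  output. No condition-specific AQ slopes exist by default, so there is
  no AQ × condition interaction in truth; a condition offset is available
  for power experiments.

Passing tests on this cohort show that the *procedures* behave correctly
on data with the assumed structure. They do not show that real
participants satisfy that structure: the generator has no reaction times,
no engagement drift, no between-block performance drop at the block
boundary (cycle 7), no item-level AQ structure, and its learners are
exactly the fitted model.

# Group-level statistics

* **Behaviour.** Event-level correctness is modelled by a binomial-logit
  mixed model with the full three-way expansion of condition × cycle ×
  centred AQ and by-participant random intercept plus condition and cycle
  slopes (`lme4::glmer`). Condition uses non-social as reference; AQ is
  grand-mean centred; effects are reported as odds ratios with Wald 95%
  CIs. If the full random structure does not converge the model drops
  correlations first, then slopes, logging each step. The random-slope
  likelihood-ratio test compares the unstructured three-effect covariance
  (6 parameters) against intercept-only (1), a 5-df chi-square.
* **Bounded parameters.** α and ρ lie in (0, 1), so their AQ models use a
  beta likelihood with logit link, fixed effects condition + centred AQ
  (optionally × condition), and a participant random intercept, fit with
  `glmmTMB` — the engine a practitioner would use for a beta GLMM, which
  integrates the random effect by the Laplace approximation. Boundary
  values are nudged inward by 10⁻⁶ (logged) rather than dropped.
* **θ.** Analysed by a Gaussian LMM (`lmerTest`, Satterthwaite df); each
  effect carries r = t/√(t² + df).
* **Win vs loss.** The paired signed-rank test is implemented directly —
  midranks, exact enumeration of all sign patterns for n ≤ 12, normal
  approximation with continuity and tie corrections beyond — with
  `stats::wilcox.test` as an independent cross-check in the tests.
  Pairing averages each parameter over the two conditions within
  participant.
* **Resampling.** The permutation test shuffles AQ across participants
  (both condition rows keep their owner's permuted score) and recomputes
  the AQ coefficient per permutation; empirical p uses the add-one rule,
  so 999 permutations give a resolution of 0.001. The bootstrap resamples
  participants with replacement as whole clusters and reports the 95%
  percentile CI. Both accept a `"mixed"` engine (the glmmTMB model) and a
  `"fixed"` engine (fixed-effects beta regression via `mgcv::gam`,
  `betar` family) — the fixed engine is an order of magnitude faster and
  is used where hundreds of replicate datasets are analysed.
* **Multiple testing.** None is applied across the six parameter models,
  mirroring per-model reporting; interpret accordingly.

# Validation layer and problem sizes

Parameter recovery simulates agents with known parameters on one
condition's 48 events and refits them. Truths are drawn uniformly over
α, ρ ∈ [0.1, 0.9] and θ ∈ [1, 20] — the behaviourally plausible range;
raw values beyond ±3 saturate the logistic and θ beyond ~20 saturates
choice behaviour at these value separations, so sampling the full
optimizer boxes would mostly probe regions the data cannot distinguish.
The acceptance level — Spearman correlation above 0.5 for the win-domain
parameters at 100 agents — is a package-defined bar for this design, not
an empirical claim from the study. Loss-domain parameters recover worse
(rarer, noisier loss feedback); they are reported, not gated.
θ estimates are rank-consistent but biased upward at 48 events (the
likelihood is flat in θ once choices are nearly deterministic); analyses
of θ should lean on ranks and signs, as the group-level models here do.

Posterior-predictive curves forward-simulate each fitted participant on
fresh schedules with fresh feedback randomness — full forward simulation,
not one-step-ahead prediction — and compare cohort mean accuracy per
cycle with the observed curve inside a Monte-Carlo band.

Statistical operating characteristics are measured on ground-truth
parameter tables drawn straight from the generator (no trial simulation
or refitting): the question they answer concerns the statistical layer,
and 200 replicate cohorts of 126 refitted sequences each would add only
estimation noise at great cost. Null rejection rates for the beta-mixed
AQ term use 500 replicates (standard error about one percentage point);
the permutation operating characteristic uses 200 replicates of 19
permutations each — the smallest count whose add-one p can reach 0.05
exactly, so the nominal rejection rate stays 5% despite the reduced
count. Replicate studies and the recovery experiment are sized (hundreds
of replicates, five 100-agent recovery experiments, 16-participant
unit-test cohorts) to keep the default test run in the minutes range on
a single CPU.

# Known limitations

* The ρ_loss identifiability problem is a property of the literal printed
  update rule; the signed default resolves it, but fitted loss-domain
  parameters remain noisier than win-domain ones at 48 events.
* θ's upward bias at task length means its absolute values should not be
  compared across studies with different event counts.
* Fitted parameters are not independent: because lower ρ_win weakens the
  value separation that θ acts on, a covariate effect generated purely on
  ρ_win can surface in *fitted* θ with the opposite sign. The analysis
  scripts exhibit exactly this on the default cohort (the generated
  positive AQ→θ_loss slope is overridden by negative leakage from the
  AQ→ρ_win effect). Covariate effects on fitted θ should therefore be
  interpreted jointly with the ρ models, not in isolation.
* The beta mixed model is fit by Laplace approximation, not adaptive
  quadrature; with two observations per participant, random-intercept
  variance estimates are rough, though fixed effects (the quantities
  analysed) are stable.
* The generator's AQ skewness (~0.5) undershoots the empirical 0.82;
  matching it would need a third free moment and is out of scope for a
  two-parameter beta-binomial.
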