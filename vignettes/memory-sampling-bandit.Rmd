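---
title: "Memory sampling and reinforcement learning in a restless bandit: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory sampling and reinforcement learning in a restless bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membandit)
```

## The scientific problem

When people repeatedly choose among options with drifting payoffs, at
least two valuation processes can drive their choices. *Temporal-difference
reinforcement learning* (RL) maintains a cached expected value per option,
nudged toward each outcome by a learning rate. *Memory sampling* instead
retrieves individual past outcomes of an option, weighted by recency, and
values the option by the retrieved evidence. The two strategies agree on
average for a well-sampled option but diverge in how they use history —
and how much each drives behavior appears to differ across people, with
memory precision and age as candidate moderators.

`membandit` implements a complete, synthetic-data-driven version of this
research program: the three-armed restless bandit task with trial-unique
mnemonic content and incidental memory probes, the hybrid
choice model and its maximum a-posteriori (MAP) fitting machinery, the
probe-triggered memory-intrusion regression, Mnemonic Similarity Task
(MST) scoring into the lure discrimination index (LDI), and the
rank-correlation analyses that relate model parameters to age and memory
precision. A cohort generator stands in for human participants, so every
stage — including parameter recovery and the Experiment-2 style
target-versus-gist dissociation — is exercisable and testable end to end.

## Task environment

**Payoff walks.** Each deck $i$ carries a payout probability (percent)
that decays toward a target center $\theta_i$ with stickiness $\lambda$
and Gaussian noise:

$$\pi_{i,t+1} = \lambda\,\pi_{i,t} + (1-\lambda)\,\theta_i + \nu,
\qquad \nu \sim \mathcal N(0, \sigma_\nu^2),$$

reflected into $[5, 95]$. Defaults: $\lambda = 0.6$, $\sigma_\nu = 8$,
centers a random assignment of $\{60, 30, 10\}$. On the first three
trials of each room the stickiness is raised to $0.95$
(`boost_mode = "stickiness"`); an alternative convention that instead
pins the best deck's payout to 100% on those trials is available as
`boost_mode = "payout100"`. We treat the stickiness version as normative
and expose the other behind the switch because the two conventions
appear in different descriptions of the task and cannot both be the
default.

**Rotation.** Centers are reassigned after the tenth trial of each room
and every 30 trials thereafter, continuing through phase 2. We implement
reassignment as a cyclic permutation taking effect at trials 11, 41, 71,
…, which guarantees the new highest-paying deck always differs from the
previous one. A known consequence of a *fixed-direction* 3-cycle is that
center assignments recur exactly every third segment; see "Known
limitations" for how this interacts with the null calibration of the
intrusion regression.

**Schedule.** Phase 1 is 180 choice trials in six 30-trial rooms, each
room with its own scene context. Phase 2 holds 180 slots: 120 choice
trials and 60 memory probes (50 referencing old learning trials, 10
novel). The pseudorandomization of probe placement is unspecified in the
task description, so we made it explicit: probes are placed uniformly at
random among the phase-2 slots subject to no probe occupying the final
slot and no two probes being adjacent — every probe is therefore
followed by a choice trial, which the intrusion regression requires. Old
probes are drawn only from each room's first ten trials (so probed items
predate that room's rotation) and are allocated as evenly as possible
across rooms (8 or 9 per room).

**Experiment variant 2.** The six contexts form three perceptually
aliased category pairs (two beaches, two forests, two mountains): rooms
1–3 cover the three categories, rooms 4–6 their foils, and rooms 3 and 4
never share a category. Payoffs are *lure-opposed*: the modal
highest-center deck of a foil room must differ from its partner's. A
fixed cyclic rotation alone cannot achieve this (three cyclic steps
return to the start, so rooms $k$ and $k+3$ share modal assignments);
`assign_lure_opposed_walks()` therefore re-realizes the walk with the
same seed and noise, inserting double cyclic steps at foil-room
rotations where needed.

## The hybrid choice model

Per deck $x$, the RL value updates only on chosen trials,
$V_{RL}(x) \leftarrow V_{RL}(x) + \alpha_{RL}(R - V_{RL}(x))$, from zero.
The sampler values deck $x$ by the expectation of its past outcomes
$R_i$ under the recency kernel
$\alpha_{s}(1-\alpha_{s})^{t-i}$ evaluated at that deck's past choice
trials $i$. Choice probabilities are a softmax over
$\beta_p\,\mathbb 1[x = x_{t-1}] + \beta_{s} V_{s}(x) + \beta_{RL} V_{RL}(x)$
with $\alpha_{RL}, \alpha_s \in [0,1]$,
$\beta_{RL}, \beta_s \in [0,20]$, $\beta_p \in [-3,3]$.

Two contracts are deliberately explicit because the model description
leaves them open:

* **Kernel normalization.** The geometric kernel does not sum to one
  over a finite history, so we renormalize it over the deck's own
  choices, making the sampler value a proper expectation (the
  "expectation-weighted average across possible samples"). The
  $\alpha_s \to 1$ limit puts all weight on the most recent sample.
* **Cold start.** A never-chosen deck takes sampler value 0, matching
  the RL initialization; both processes are thus symmetric before the
  first choice of a deck.

Missing responses contribute nothing to the likelihood, advance neither
learner, and clear the perseveration indicator (as does the first
trial). The softmax subtracts the maximum logit, so probabilities are
invariant to constant logit shifts. The per-trial recursion is compiled
(C++); the test suite pins it to a plain-R composition of the exported
single-step operations and to a brute-force kernel enumeration at
$10^{-10}$.

## MAP fitting

Optimization is unconstrained (BFGS) over coordinates mapped into the
parameter boxes by scaled logistics, with priors evaluated on the
bounded scale: $\mathrm{Beta}(1.1, 1.1)$ on both learning rates and
$\mathcal N(0, 10)$ truncated to the respective boxes on the three
weights. Restarts draw starting points uniformly from $[-3, 3]$ per
unbounded coordinate (which covers most of each box through the
logistic) and stop once the best objective has been stable for five
consecutive runs (change below $10^{-6}$), capped at 30 runs. Failed
runs are skipped. Fits are reproducible from their seed.

The chance-model exclusion rule is a likelihood-ratio test against the
fixed $P = 1/3$ model on 5 degrees of freedom at $\alpha = 0.05$; the
test statistic uses the likelihood at the MAP point. The exclusion rule
is stated only as dropping participants whose fits are no better than
chance; the specific nested LR test is our choice, as the standard
reading of that comparison.

## Intrusion regression

For each deck and each phase-2 choice trial the design matrix stacks:
previous-trial deck identity (DI), deck-chosen-and-rewarded at lags 1–3
(DR; lags crossing the phase boundary draw on late phase-1 trials, lags
before trial 1 are zero), and — only on trials immediately following an
old-item probe — probed-deck identity (EI), probed-deck-rewarded (ER),
and the evoked context reward (EC) of the probed room, where
$EC^{C,i} = (\#\text{wins} - \#\text{losses}) / \#\text{choices of } i
\text{ in } C$. A deck never chosen in the probed room takes
$EC = 0$, the uninformative midpoint. Trials following novel probes
carry zero probe regressors; missing-response trials contribute no
rows. The default schedule yields 360 rows and 7 regressor columns.

The variant-2 analysis adds a gist column: EC pooled over the probed
room and its same-category foil, then *serially orthogonalized* against
the target EC column (projection removal, no centering, no rescaling of
the target). The matrix is fit as one stacked logistic regression with
coefficients shared across the three deck parts — the stated matrix
dimensions describe a single matrix — with a per-fit intercept that is
not reported among the named regressors (omitting it would bias the
slopes); a per-deck variant is available behind a flag. Separated fits
fall back to a weakly ridge-penalized logistic fit and are flagged.
Coefficients are tested against zero across participants by two-tailed
one-sample t-tests.

## MST response model and LDI

The MST session is 128 study items and 192 test items in equal thirds
of repetitions, lures, and foils. LDI is
$p(\text{"similar"}|\text{lure}) - p(\text{"similar"}|\text{foil})$
over responded trials. The synthetic response model is a three-state
confusion matrix with one precision parameter $p$ and fixed guessing
rates: repetitions are precision-independent; lures have
$p(\text{similar}) = 0.10 + 0.70\,p$; foils are fixed with
$p(\text{similar}) = 0.10$. Expected LDI is therefore exactly
$0.70\,p$ — any monotone model suffices because the analyses use MST
only through LDI, and this one has a closed form the tests can pin.

## The synthetic cohort

The generator defines the study conditions; its defaults are fixed
choices, not dials:

* Ages uniform over 18–77.
* Latent precision $= 0.78 - 0.38\,a + \mathcal N(0, 0.16)$ (clamped to
  $[0,1]$), with $a$ the age normalized to $[0,1]$. Age thus explains
  roughly a third of precision variance ($r \approx -0.57$), in line
  with published LDI–age relationships, and crucially leaves genuine
  age-independent precision signal — the headline analyses require the
  precision→sampling link to survive age residualization *in the ground
  truth*, which a near-collinear mapping cannot encode.
* $\beta_{s} = 1 + 6\,\text{precision} + \mathcal N(0, 0.75)$;
  $\beta_{RL} = 7.5 - 5\,a + \mathcal N(0, 1)$;
  $\beta_p = -0.6 + 1.4\,a + \mathcal N(0, 0.25)$ (all clamped to their
  boxes); learning rates uniform on realistic sub-ranges
  ($\alpha_{RL} \in [0.2, 0.6]$, $\alpha_s \in [0.3, 0.8]$); probe
  recognition accuracy $0.6 + 0.35\,\text{precision}$.
* Probe biases are additive in logits on the choice trial right after an
  old probe: `b_item` on the probed deck, `b_ctx` on each deck's EC in
  the probed room, `b_gist` on the category-pooled EC (variant 2). The
  additive-logit form mirrors the regression's linear form, so the
  regression has a well-posed recovery target; the original analyses
  provide no generative account of probe bias, making this an explicit
  modeling choice.
* Each agent receives its own seeded schedule and walk. (The original
  task pre-generated four payoff series per experiment; we give each
  agent its own because variant-2 lure opposition depends on the
  agent's room–category pairing, which differs across agents.)
* Generative choices use the expectation-form sampler value — the same
  quantity the likelihood uses — so recovery is well-posed; a
  single-draw sampling simulator is deliberately *not* used at fit time.

What the generator does **not** emulate: reaction times, attrition,
lapses/missing responses, within-session drift of attention, or manual
quality-control exclusions. Passing tests therefore validate the
machinery and its statistical behavior under the model's own
assumptions, not the claim that human data would behave identically.

## Numerical choices

Softmax with max-logit subtraction; sampler recursion carries per-deck
numerator/denominator in units of the most recent sample's weight
(exact for $\alpha_s \in [0,1]$ including both endpoints); logistic
transforms error at the box boundaries (no finite preimage); restart
stability means an objective change below $10^{-6}$; ridge fallback for
separated logistic fits uses $\lambda = 10^{-3}$ without
standardization; Kendall p-values use the normal approximation
throughout (ties are expected); the Fisher comparison of correlations
uses $SE = \sqrt{1/(n_1-3) + 1/(n_2-3)}$ after the
$R = \sin(\pi\tau/2)$ mapping; residualization applies to the
model-parameter variable, with a both-sides variant behind a flag.

## Problem sizes used in the checks

The packaged checks use 100 agents for full-range parameter recovery,
one 50-agent cohort for regression signal recovery, 40 cohorts of 50
agents for the null calibration, two 40-agent variant-2 cohorts for the
target-versus-gist dissociation, and one 200-agent lifespan cohort for
the headline correlations. These sizes were chosen to give each check
clear statistical resolution while keeping a full run of the suite
comfortably reproducible on a single CPU.

## Known limitations

* **Identifiability of the two weights at extreme values.** The TD value
  and the sampler expectation are correlated statistics of the same
  reward history, and both live in $[0,1]$, so inverse temperatures in
  the upper half of $[0, 20]$ saturate the softmax: 180 binary-outcome
  trials cannot rank-order, say, $\beta = 12$ versus $\beta = 18$, and
  the posterior trades $\beta_{RL}$ against $\beta_s$ along a ridge.
  Full-range uniform recovery of the two weights therefore plateaus
  around Kendall $\tau \approx 0.35$–$0.45$ (the MAP point reliably
  attains a posterior at least as high as the generating parameters —
  this is an information limit, not an optimizer failure). Recovery is
  substantially better when generative parameters are drawn from the
  model's own priors, which down-weight the saturated region.
* **Null calibration of the intrusion regression.** With a
  fixed-direction cyclic rotation, a deck's payoff standing recurs every
  third segment, so the probed room's EC is mildly positively related to
  the deck's current standing even with zero generative probe bias;
  lag-1–3 reward controls cannot fully absorb this, and the population
  tests on the probe terms reject at roughly 10% rather than the
  nominal 5%. This is a structural property of the rotation design
  interacting with any value-driven agent.
* **The walk's reflected mean.** The deck centered at 10 sits about 0.56
  stationary SDs above the lower bound, and reflection inflates its
  long-run mean to about 14.5; decks centered at 30 and 60 sit within
  noise of their centers.
* The MST response model is a stand-in with a convenient closed form; it
  is monotone in precision by construction, which is all the analyses
  require, but it is not a fitted psychometric model.
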