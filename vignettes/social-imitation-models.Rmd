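---
title: "Modelling imitation in social reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling imitation in social reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialrl)
```

## The task and the scientific question

`socialrl` studies how a human *Learner* integrates the choices of a
*Demonstrator* into reward learning on a two-armed bandit. On **private**
trials the Learner picks one of two symbols and wins or loses a point
(coded $r \in \{+1, -1\}$); on **observational** trials the Learner only
sees which symbol the Demonstrator picked — never the Demonstrator's
outcome, so vicarious reinforcement is excluded by design. Demonstrations
arrive in runs of 1–7 consecutive trials, which makes it possible to ask
whether social influence *accumulates* over successive demonstrations and
*propagates* over successive private choices.

The package implements three competing hypotheses about where the
demonstration enters the learning algorithm, each as a family of concrete
variants, plus a no-imitation baseline:

* **RW** (baseline): Rescorla–Wagner learning from own outcomes only,
  $Q(c) \leftarrow Q(c) + \alpha_p\,(r - Q(c))$. `RW2` additionally moves
  the unchosen option toward $-r$ (symmetric update).
* **DB** (decision biasing): the demonstration transiently biases the next
  choice without touching $Q$. Variants cross the bias target (policy
  $\pi$, decision values $Q'$, symmetric $Q'$) with whether consecutive
  demonstrations accumulate in the trace (`DB1`–`DB3` re-derive from $Q$
  at every demonstration; `DB4`–`DB6` keep the trace alive across an
  observational run). All traces are cleared by the next private choice.
* **MB** (model-based imitation): the Learner estimates the Demonstrator's
  preferences ($\pi_D$ by policy update, or $Q_D$ by (symmetric) value
  update, learning rate $\alpha_d$) and biases its own action selection
  toward the model's preferred symbol with magnitude $\alpha_i$
  (`MB1`–`MB9`, the $3\times3$ cross of model-update and bias-step types).
* **VS** (value shaping): the demonstrated symbol is a surrogate reward
  written directly into the value function,
  $Q(d) \leftarrow Q(d) + \alpha_i\,(1 - Q(d))$, and for `VS2` also
  $Q(\bar d) \leftarrow Q(\bar d) + \alpha_i\,(-1 - Q(\bar d))$.
* **metaVS**: value shaping with a *per-state* imitation rate
  $\alpha_i(s)$, initialized at 0 and driven by agreement
  ($\tau = 1$ iff $Q(d) = \max(Q(d), Q(\bar d))$, ties counting as
  agreement):
  $\alpha_i(s) \leftarrow \alpha_i(s) + \alpha_m\,(\tau - \alpha_i(s))$.
  The free parameter is $\alpha_m$; $\alpha_i$ is not fitted.

Action selection everywhere is a softmax with choice autocorrelation,

$$\pi(c) = \frac{1}{1 + e^{\beta\,[Q(\bar c) - Q(c) - \lambda(c)\,\kappa]}},$$

with $\lambda(c) = +1$ if $c$ was the last performed action, $-1$
otherwise, and 0 before the first action in a context.

## Parameters

| parameter  | meaning                               | range    | notes |
|------------|---------------------------------------|----------|-------|
| `alpha_p`  | private reward learning rate          | (0, 1)   | free in every model |
| `alpha_i`  | imitation rate / decision bias        | (0, 1)   | (-1, 1) with `allow_negative_imitation`; not free in metaVS |
| `alpha_d`  | demonstrator-model learning rate (MB) | (0, 1)   | fixed at 0.1 by default; the fixed version fits better than the free one, so fitting it is behind `alpha_d_fixed = FALSE` |
| `alpha_m`  | meta learning rate (metaVS)           | (0, 1)   | |
| `beta`     | softmax inverse temperature           | (0, 100] | per-point value scale |
| `kappa`    | choice autocorrelation weight         | [-10, 10] | positive = perseveration |

All values, traces and demonstrator models are bounded in $[-1, 1]$ by
construction (targets are $\pm 1$ or $\pm r$), so `beta` is measured per
point of value difference.

## What the generator emulates — and what it does not

`task_config()` ships three designs: a 400-trial within-subject design
(four sessions of five 20-trial blocks: one private, two skilled- and two
unskilled-demonstrator blocks; stable 0.7/0.3 contingencies; 1:1
observational:private ratio), a 300-trial between-subject design (0.6/0.4,
one demonstrator group per subject), and a 300-trial restless-bandit
design in which both symbols' win probabilities follow independent
reflected Gaussian random walks (start 0.5, step sd 0.03, bounds
[0.2, 0.8] — the walk parameters are not pinned down by the source
designs, so these defaults are documented and configurable) with a 1:2
observational:private ratio and demonstrator correct rates 0.84/0.60.
Skilled and unskilled demonstrators pick the currently reward-maximizing
symbol 80% and 20% of the time.

Two generator decisions deserve emphasis:

* **Quota-based demonstrations under stable contingencies.** Within an
  observational block the design constrains demonstrations to runs of at
  most 7 trials with at most 3 consecutive same-option demonstrations.
  Drawing per-trial Bernoulli(skill) symbols and rejecting sequences that
  violate the run limit would silently depress the realized correct rate
  far below the nominal skill, because the rejected sequences are exactly
  the correct-heavy ones (the correct symbol is constant within a block).
  A controlled demonstrator that is "80% correct" under these constraints
  must therefore place a fixed quota — `round(skill * n_obs)` correct
  demonstrations per block — and arrange their order among the sequences
  that satisfy the limit, which is what `make_schedule()` does. Under
  random walks the correct symbol varies trial by trial, the constraint is
  absent, and demonstrations are independent Bernoulli(skill) draws.
* **No same-option limit in the random-walk design.** The run limit
  belongs to the computer-controlled designs; the walk design replays
  free demonstrator behavior, where long same-option runs are expected
  (a 0.84-correct demonstrator tracking a slowly drifting best option
  produces them constantly, and no rejection sampler can avoid them). The
  limit is therefore `Inf` by default for `exp3` and active for
  `exp1`/`exp2`.

What the synthetic cohorts do *not* emulate: real participants' lapses and
attention drifts, any session-order or fatigue effects, deception-driven
social dynamics, and the recorded (non-stationary, autocorrelated)
demonstrator traces of the walk-design source experiment, which we stand
in for with Bernoulli policies at the reported skill levels. Passing
recovery and signature tests on these cohorts therefore demonstrates that
the *pipeline* is correct and the model space identifiable under the
designs — not that any particular model explains real human data.

## Fitting, priors, and the evidence scale

`fit_subject()` minimizes the negative log-likelihood summed over private
trials only (the forced matching response on observational trials carries
no choice information; it influences the fit only through state
evolution). Optimization is bounded `L-BFGS-B` with 10 restarts drawn
from the priors; the best restart wins, ties by first. Choice
probabilities are floored at $10^{-12}$ inside the log so boundary
parameters cannot produce infinite objectives.

MAP fitting (`objective = "lpp"`) adds the priors: gamma(shape 1.2,
scale 5) on `beta` and beta(1.1, 1.1) on every learning rate. The gamma's
second argument is read as a *scale* (prior mean 6, a typical inverse
temperature); a rate reading would put the prior mass below 0.5, which no
fitted cohort resembles. `kappa` has a flat prior contributing zero;
restart draws and recovery cohorts sample it uniformly from (-1, 1), the
plausible perseveration range, while the fitting bounds remain [-10, 10].

The evidence approximation follows the source convention
`aic(nll, p) = -nll - p`: a log-evidence-scale quantity (larger is
better), equal to the conventional AIC divided by $-2$. It is fed
directly into `rfx_bms()`, which treats model identity as a random effect
across subjects: a variational Dirichlet scheme (uniform prior
$\alpha_0 = 1$, responsibilities
$u_{nk} \propto \exp(l_{nk} + \psi(\alpha_k) - \psi(\Sigma\alpha))$,
iterated until the largest change in $\alpha$ falls below $10^{-4}$)
yields expected model frequencies $\alpha/\Sigma\alpha$; exceedance
probabilities come from $10^6$ seeded Dirichlet draws, or exactly from
the Beta CDF when only two models are compared.

## Design choices that were genuinely open

* **Perseveration and the forced matching response.** Participants press
  a key to match the demonstration, so one could let the demonstrated
  symbol count as the "last performed action" for the $\kappa$ term. We
  default to *not* doing so (`obs_match_last_action = FALSE`): the match
  is forced rather than chosen, and — decisively — counting it breaks the
  exact reduction $\alpha_i = 0 \Rightarrow$ RW for the policy-trace DB
  variants, because their trace freezes the perseveration term at
  demonstration time while the baseline evaluates it at choice time. The
  exact reduction is a property we enforce at machine precision for every
  social model; the alternative remains available as a switch.
* **MB bias functional.** The demonstrator model's *preferred* symbol
  (argmax of $\pi_D$ or $Q_D$) is treated as a pseudo-demonstration on
  every private trial, applied with the variant's bias step; exact ties
  produce no bias. The alternative — blending the learner's policy toward
  $\pi_D$ — is less parsimonious (it needs a mixing functional that the
  three bias-step types already provide) and was not adopted.
* **DB trace lifetime.** Traces are re-derived from $Q$ at every
  demonstration for `DB1`–`DB3`, persist across consecutive observational
  trials for `DB4`–`DB6`, and are invalidated by every private choice.
  This reproduces the intended accumulation-without-propagation
  signature: the accumulating variants keep both preceding demonstrations
  in the trace, and no variant's bias survives a private choice.
* **metaVS tie rule.** $Q(d) = Q(\bar d)$ satisfies the max condition, so
  $\tau = 1$: the very first demonstration in a fresh context counts as
  agreement. This is the literal reading of the update and gives the
  imitation rate a warm start proportional to $\alpha_m$.
* **Update order.** On observational trials the demonstrator-model /
  meta-rate update precedes any value or trace change; metaVS evaluates
  $\tau$ against the pre-update $Q$.

## Numerical choices and degenerate inputs

Probability floor $10^{-12}$; parameter bounds offset from 0/1 by
$10^{-6}$; softmax exponent clamped at $\pm 700$ to avoid overflow at
extreme `beta`; optimizer tolerance $10^{-6}$ (relative) on the
objective; variational convergence $\Delta\alpha < 10^{-4}$ with an error
(not silent truncation) at 500 iterations. Degenerate inputs raise
informative errors: observational trials without demonstrations, outcomes
outside $\{+1, -1\}$, infeasible interleaving constraints, all-zero
paired differences in the Wilcoxon wrapper, constant observed choices in
the posterior-predictive correlation (flagged per subject rather than
propagating `NA`s).

## Problem sizes

The shipped tests and the acceptance script use cohorts of 20 subjects
per generating model (four-model recovery on the 300-trial
between-subject design, 10 restarts per fit), 40 subjects for parameter
recovery on the 400-trial design, 30-subject simulated cohorts for the
behavioral-signature orderings, and 50–100 generated schedules for the
design-fidelity checks. These sizes are the package's own choice of a
desk-scale replication: large enough that exceedance probabilities
saturate and rank correlations stabilize, small enough to re-run
routinely.

## Known limitations

* The variational selection implements plain exceedance probabilities,
  not protected ones, and no family-level inference.
* Fitting is per-subject maximum likelihood / MAP, not hierarchical.
* Only single-state (bandit) tasks: no sequential credit assignment, and
  demonstrator outcomes are never modelled (by design of the task).
* The walk-design demonstrators are Bernoulli stand-ins for recorded human
  traces; analyses that depend on the autocorrelation of real
  demonstrator behavior are out of scope.
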