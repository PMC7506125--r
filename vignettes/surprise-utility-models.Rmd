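---
title: "Surprise-sensitive utility models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprise-sensitive utility models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surpriseRL)
```

## The models

All four models in this package are Rescorla–Wagner learners: each
stimulus (slot machine, bandit arm) carries an action value $Q$ that is
updated after every experienced outcome, and choices among offered
stimuli follow a softmax with inverse temperature $\beta$,

$$P(a(t) = i) = \frac{\exp(\beta Q_i(t))}{\sum_j \exp(\beta Q_j(t))}.$$

The learning rate carries an exposure-decaying bonus,
$\alpha' = \alpha + 0.5/(1 + T_s)$, where $T_s$ counts how many times
stimulus $s$'s outcome has been experienced. The bonus makes the first
few outcomes dominate early learning (the very first update has
$\alpha' = \alpha + 0.5$) and decays to the base rate, which also makes
the models nearly indifferent to how $Q$ is initialised. For the plain
bandit simulations we use the constant-rate variant (`decay = FALSE`,
the default on Bernoulli bandit tasks), where $\alpha' = \alpha$.

The four learning rules differ only in the target of the update for the
chosen stimulus:

* **Q-learning**: $Q \leftarrow Q + \alpha' (r - Q)$.
* **Utility**: the outcome passes through a nonlinear utility with
  anchors $U(0) = 0$, $U(20) = 20$, $U(40) = 20a$;
  $Q \leftarrow Q + \alpha' (U(r) - Q)$. With $a = 2$ this is exactly
  Q-learning on the risky task's payoffs.
* **Risk-sensitive Q-learning**: separate rates for the sign of the
  prediction error, $\alpha^+$ for $r > Q$ and $\alpha^-$ for $r < Q$
  (a zero prediction error moves nothing under either rate).
* **Surprise-sensitive utility**: the outcome value is reduced in
  proportion to the surprise, i.e. the absolute prediction error,
  $$S(t) = r(t) - d\,|r(t) - Q(t)|, \qquad
    Q \leftarrow Q + \alpha' (S(t) - Q).$$
  $d \in [-1, 1]$ is the surprise decay rate; $d = 0$ recovers
  Q-learning exactly (a property the test suite checks bit-for-bit).

Parameter boxes: $\alpha, \alpha^\pm \in [0,1]$, $\beta \in [0,10]$,
$a \in [1,30]$, $d \in [-1,1]$.

### Why surprise produces risk aversion

On the risky probabilistic learning task the risky stimulus pays 0 or
40 cents with equal probability, so at its long-run value ($Q \approx
20$) every outcome is surprising by about 20 cents; the sure stimuli
are eventually never surprising. Positive $d$ therefore depresses the
risky stimulus's value relative to a sure 20, and the agent's
probability of taking the sure option on the 30 diagnostic
\{sure 20 vs risky\} trials rises with $d$ — more steeply the faster
the agent learns.

### Degenerate points of the surprise rule

Two structural facts matter for simulation design and are easy to miss:

1. **$d = 1$ with a zero start freezes learning.** Whenever
   $r \ge Q$, $S = r - (r - Q) = Q$: the update target equals the
   current value. With all values initialised at 0 and non-negative
   payoffs, *no value can ever move* at $d = 1$, and the agent stays at
   chance forever. The published monotone increase of risk aversion in
   $d$ up to 1 is therefore only reproducible with an informative
   start. The risky-task builder initialises values at 20 cents (the
   risky option's expected value and the middle sure payoff); because
   of the decayed learning rate this choice is inert away from the
   degenerate point. Bandit tasks keep a zero start.
2. **Downward learning is amplified, upward learning damped.** For
   $r > Q$ the effective step is $(1-d)\,\alpha'(r - Q)$; for $r < Q$
   it is $(1+d)\,\alpha'(r - Q)$. Surprise-sensitive agents forget
   good news slowly but punish bad news quickly — the asymmetry behind
   most of the behavioural signatures below.

## Tasks

* `risk234` / `build_risk_task()`: the 234-trial risky probabilistic
  learning task. Five stimuli (sure 40, sure 20, two distinct sure-0
  stimuli, and the 0/40 risky stimulus); 130 choice trials in five pair
  types plus 104 forced single-stimulus trials, shuffled by one seeded
  uniform permutation and cut into three 78-trial blocks. Learning
  state persists across blocks; the two 0-cent stimuli have separate
  values and exposure counts; forced trials deliver outcomes and drive
  learning but contribute no choice likelihood. Rewards are in cents.
* `bandit2` / `build_bernoulli_bandit()`: all-choice-trial bandits;
  arm $i$ pays $r_i$ with probability $p_i$, else 0. Default 500
  trials with $p = (0.8, 0.2)$, unit rewards.
* `gauss4` / `build_gaussian_bandit()`: four arms with a common mean
  payoff (250 euros) and spreads 0/10/30/70, 200 trials, untruncated
  normal draws. The preset applies a reward scale of 0.01 so that
  $\beta Q$ stays in a workable range given the $[0,10]$ box on
  $\beta$; any fitted $\beta$ must be reported together with the
  reward scale, since the two only act through their product.

## Simulation experiments

`experiment_fig2_sweep()` sweeps the surprise model over
$d \in \{0, 0.25, 0.5, 0.75, 1\}$ and $\alpha \in \{0.2, 0.5, 0.8\}$
on the risky task (1,000 agents per cell in the acceptance runs, each
with its own trial-order permutation) and records the mean sure-choice
probability. Such sweeps are conventionally run at the median of
subject-level fitted $\beta$, a dataset-dependent quantity. We fixed
$\beta = 0.05$ (cent units): in a scan of the plausible cent-scale
range this is the regime in which both characteristic orderings — the
monotone rise in $d$ and the steeper rise at higher
$\alpha$ — are expressed; at $\beta \ge 0.1$ the sure-choice
probability saturates near 1 by $d = 0.75$ and the ceiling inverts the
$\alpha$ ordering. With $\beta = 0.05$ the sweep spans roughly 0.5 to
0.9, matching the range such experiments report.

`experiment_fig4_stay()` contrasts Q-learning and the surprise model
($\alpha = 0.3$, $\beta = 2$, $d = 0.5$, constant learning rate) on
the 0.8/0.2 bandit through the stay probability: the chance of
repeating the current choice, stratified by whether the previous and
current outcomes were rewarded. Conditioning uses the reward history
only — no constraint that the same option was chosen at $t-1$ —
and a reward counts as such when strictly positive. The surprise model
stays less after rewarded trials, most prominently after a *surprising*
reward ($r(t-1) = 0$, $r(t) = 1$); `experiment_fig5_dsweep()` shows the
rewarded-trial stay probability falling monotonically in $d$.

`experiment_fs5_safe()` probes two safe-option bandits (both arms
$p = 0.9$) with small (1 vs 0.8) and large (1 vs 0.3) reward gaps. With
a small gap, surprise shrinks both values nearly uniformly, which acts
like a lower $\beta$: the surprise model picks the better arm *less*
often. With a large gap the direction reverses — but, as the
fixed-point analysis in the function's documentation shows, only
transiently: at steady state per-option surprise rescales both arms'
values by the common factor $(1-d)/(1-d(2p-1))$ and always shrinks the
gap. The reversal arises while the rarely-chosen low arm still holds a
stale, optimistic value whose large prediction error is amplified by
surprise. The experiment therefore runs in that regime by default:
values start at 1 (the large reward), $\alpha = 0.05$, 100 trials. The
effect is small (about half a percentage point) and needs a few
thousand agents to resolve.

Standard errors in all summaries are between-agent (across-subject)
standard errors of per-agent means.

## Fitting and model evidence

`map_fit()` maximises the log posterior — choice-trial softmax log
likelihood plus log priors — with box-constrained L-BFGS-B from the
prior mode plus seeded prior draws (default 10 starts). Priors follow
the behavioural-fitting conventions for this task family: Beta(2,2) on
learning rates, Gamma(shape 2, scale 3) on $\beta$ (mode 3, well
inside the $[0,10]$ box; a `beta_param = "rate"` switch covers the
other reading of the ambiguous notation), uniform on $a$ and $d$.
Densities are not renormalised for box truncation: the constants are
shared across models for shared parameters and never move the MAP.
Forced trials drive state but add no likelihood term, so a
forced-trials-only session returns the prior modes — a property the
tests use directly.

The log marginal likelihood is approximated by Laplace's method at the
MAP $\hat\theta$:
$$\log p(D\,|\,M) \approx \log p(D, \hat\theta) +
  \tfrac{k}{2}\log 2\pi - \tfrac12 \log \det H,$$
with $H$ the Hessian of the negative log posterior, computed by central
finite differences with a relative step of $10^{-4}$ per coordinate.
Modes within $10^{-4}$ of a box edge are nudged $10^{-4}$ inside before
differentiation and flagged (`boundary = TRUE`). Because the surprise
and risk-sensitive rules contain absolute-value/sign kinks, the log
posterior is only piecewise smooth and a narrow stencil can straddle a
kink: if the Hessian is not positive definite the step is widened
(5×, 25×) before a last-resort ridge is applied with a warning (e.g.
for a genuinely flat direction under a uniform prior with no
identifying data).
The acceptance suite checks the approximation against brute-force grid
quadrature of the 2-parameter posterior on a 50-trial session (within
0.1 nats) and against the exact Gaussian closed form.

## Group-level model selection

`bms()` implements random-effects selection from a subjects × models
log-evidence matrix: a variational Dirichlet posterior over population
model frequencies (fixed-point iteration on responsibilities
$g_{nk} \propto \exp(l_{nk} + \psi(\alpha_k) - \psi(\alpha_\Sigma))$
and counts $\alpha_k = \alpha_0 + \sum_n g_{nk}$, prior count
$\alpha_0 = 1$), Monte-Carlo exceedance probabilities (default $10^6$
seeded Dirichlet draws; exact Beta tail available at $K = 2$), the
Bayes omnibus risk $\mathrm{BOR} = (1 + e^{F_1 - F_0})^{-1}$
comparing the variational free energy $F_1$ against the equal-frequency
null $F_0 = \sum_n \log \frac1K \sum_k e^{l_{nk}}$, and the protected
exceedance probability
$\mathrm{pXP}_k = (1-\mathrm{BOR})\,\mathrm{XP}_k + \mathrm{BOR}/K$.
Under exactly symmetric evidences $F_1$ sits below $F_0$ by the
Dirichlet KL term, so the BOR approaches 1 and the pXP is uniform —
the no-winner behaviour the tests assert. `one_sample_t()` covers the
accompanying subject-level test of whether the fitted surprise decay
rate is positive.

## Synthetic cohorts

`generate_cohort()` is the stand-in for the two behavioural datasets
the models were developed on: 16-subject, 234-trial risky-task cohorts
and 163-subject, 200-trial four-armed Gaussian-bandit cohorts are both
a single `cohort_spec()` away. Per-subject parameters default to
uniform draws over each box, except $\beta$, which uses its Gamma prior
truncated to $[0,10]$ so that near-zero-temperature subjects (whose
data identify nothing) stay rare. Subject seeds derive from the master
seed by a counter scheme, making any subject individually re-runnable.
What the generator does *not* emulate: reaction times, missed trials,
within-session non-stationarity, or any subject covariates — so
passing recovery tests certify the fitting machinery, not the
behavioural realism of the cohorts.

`recovery_experiment()` (truth vs MAP estimates, per-parameter Pearson
correlations) and `model_recovery_experiment()` (fit all models,
select by pXP, tabulate confusions) validate the pipeline end to end.
At the study's scale — 50 risky-task subjects with
$d \sim U(0,1)$ — the surprise decay rate recovers with
$r(d, \hat d) \approx 0.9$.

## Numerical choices and problem sizes

* Softmax probabilities and likelihoods are computed with
  max-subtraction; evidence aggregation uses log-sum-exp.
* The optimizer box is shrunk by $10^{-6}$ on edges where a prior
  density vanishes (Beta at 0/1, Gamma at 0).
* $\alpha'$ is not capped at 1 by default (`clip = TRUE` is
  available): early-exposure updates may overshoot their target, which
  is what the printed update rule does.
* The variational fixed point iterates to
  $\max_k |\Delta\alpha_k| < 10^{-6}$ (cap 1,000 iterations).
* Acceptance-scale runs use 1,000 agents per simulation cell
  (3,000 for the half-point safe-option effect), 100 random sessions
  for the exact nested-model identities, a $601 \times 1201$
  quadrature grid for the evidence oracle, 50 subjects for
  $d$-recovery, and 16 subjects × 4 models for the selection
  pipeline; unit tests use smaller versions of the same constructions.

## Known limitations

* The utility model's anchors define it only on the risky task's
  \{0, 20, 40\} payoffs; for continuous outcomes the package
  substitutes the power law $U(x) = 20\,(x/20)^{\log_2 a}$ through the
  anchors (odd-extended to negative outcomes). This is an
  extrapolation, flagged as such in the documentation.
* The safe-option preference reversal exists only in the
  early-learning regime described above; the package's steady-state
  analysis shows it cannot occur asymptotically under this model.
* Laplace evidence degrades for boundary or flat modes; such fits are
  flagged rather than silently accepted.
* No hierarchical (random-effects over parameters) estimation and no
  choice-kernel/perseveration terms; adapters for the original
  datasets' file formats are out of scope, so external refits require
  writing a reader against the downloaded files.
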