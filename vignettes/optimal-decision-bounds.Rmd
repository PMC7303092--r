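---
title: "Reward-rate optimal decision bounds in an expanded judgment task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-rate optimal decision bounds in an expanded judgment task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optbound)
```

## The decision problem

`optbound` models a two-alternative expanded judgment task.  Two stimuli
flash as independent Bernoulli processes in discrete time: the *target*
flashes with rate $\theta_T$ per step, the *distractor* with rate
$\theta_D \le \theta_T$, and the observer must decide which side carries the
target.  Each step produces one of four observations — only the left
stimulus flashes, only the right, both, or neither.  Under the hypothesis
"left is target" their probabilities are
$p = \theta_T(1-\theta_D)$, $q = \theta_D(1-\theta_T)$,
$\theta_T\theta_D$, and $(1-\theta_T)(1-\theta_D)$; the opposite hypothesis
swaps the rate roles.  Only the two single-flash events discriminate the
hypotheses when the rates are known, so task difficulty is governed by the
gap $p - q$.

A trial lasts at most $T = 30$ steps.  A correct commitment earns
$+1000$ points, an incorrect one $-500$; every additional observation costs
$c(t)$ points, with the logistic schedule

$$c(t) = \frac{74.92217}{1 + e^{\,3 - t/10}}$$

for the *increasing* cost direction and its time reversal
$c(T + 1 - t)$ for the *decreasing* direction.  The amplitude is calibrated
so the cumulative cost over a full trial is 500 points.  Failing to commit
by the deadline is an all-in timeout worth $-1000$ points — the 500 points
of fully accrued sampling costs plus the 500-point error penalty.  With a
fixed trial length and inter-trial interval the denominator of the reward
rate is constant, so the package maximises and reports *expected net
reward* (reward minus sampling costs); a rate-mode divisor is available via
`rr_spec()` and never changes any policy ordering.

## Belief updating

Starting from the unbiased prior $\pi(0) = 0.5$, the posterior belief
$\pi(t)$ that the left stimulus is the target evolves by Bayes' rule.

**Known rates (`K = Inf`).**  Double-flash and no-flash observations have
equal likelihood under both hypotheses and leave $\pi$ unchanged, so the
signed net evidence count $d$ (lone-left minus lone-right flashes) is a
sufficient statistic and $\pi = (p/q)^d / (1 + (p/q)^d)$.

**Beta-uncertain rates (finite `K`).**  The observer's uncertainty about
each rate is a beta prior with $\alpha_i = \theta_i K$,
$\beta_i = (1-\theta_i)K$; `K` acts as a number of prior observations, and
the prior mode sits at the true rate.  The likelihood of the observation
history is marginalised over the rates, which makes the per-side flash
counts $(k_l, k_r)$ the sufficient statistic and gives each hypothesis a
product of beta-binomial sequence marginals,
$m_i = \prod_{\text{side}} B(\alpha + k,\ \beta + t - k)/B(\alpha, \beta)$,
evaluated in log space with `lbeta`.  One design choice deserves note: a
literal per-step application of fixed beta priors would reproduce the
known-rate update exactly (the prior means equal the true rates), so the
package implements the coherent full-history marginalisation in which the
beta posteriors advance with the counts.  This is what makes
non-discriminating observations informative under uncertainty — a
double flash shifts both rate posteriors upward and can move $\pi$ — and it
is the only reading under which the precision `K` matters at all.
As `K` grows the uncertain posterior converges monotonically to the
known-rate posterior (tested over every state up to the full horizon).

The one-step predictive mixes the two hypothesis-conditional predictives
with the current posterior; under uncertainty the conditional flash
probabilities are the beta-posterior means $(\alpha + k)/(K + t)$.  Under
this predictive the posterior is a martingale, which the tests assert to
`1e-10` on all reachable states.

## The optimal dynamic bound

The optimal decide-left / decide-right / wait policy is computed by
finite-horizon backward induction over the belief-state lattice — $(t, d)$
for known rates ($O(T^2)$ states), $(t, k_l, k_r)$ for uncertain rates
($\sim T^3/3$ states).  Committing at belief $\pi$ is worth
$1000\,\pi - 500\,(1-\pi)$ for the favoured side (sunk costs excluded);
waiting from $t$ charges $c(t+1)$ and takes the expectation of the
successor values under the decision-maker's own predictive.  At the
deadline the two decide actions are compared directly, because guessing
(worth $+250$ at $\pi = 0.5$) always dominates the timeout outcome.

Accounting conventions, chosen to make the bookkeeping exactly consistent:

* deciding is allowed at $t = 0$, before any observation, at zero cost, so
  a decision after $T_d$ observations has paid exactly
  $C(T_d) = \sum_{t=1}^{T_d} c(t)$;
* the $-1000$ timeout is booked internally as a terminal $-500$ on top of
  the sunk $C(30) = 500$, avoiding double counting;
* ties are broken deterministically: deciding beats waiting on exact value
  ties, and at $\pi = 0.5$ the two decide actions are value-equivalent —
  the left side is reported and the state flagged as a tie;
* the right-decision value is constructed as the exact floating-point
  mirror of the left one and the continuation value is averaged with its
  mirror image, so the policy's left-right symmetry holds exactly in
  floating point rather than to rounding error.

The criterion curve $\delta_l(t)$ is the projection of the policy onto the
posterior scale: the smallest $\pi$ among decide-left states at each step,
undefined while no lattice state has crossed the implicit bound (early in
a trial the reachable posteriors are few and may all sit in the wait
region).  For known rates the decide region is provably an upper set in
$|d|$ and the extraction records a threshold-consistency flag, always true
there; under uncertainty $\pi$ need not be a sufficient statistic for the
optimal action, and the flag reports any violations rather than hiding
them.  Increasing costs produce a monotonically collapsing bound; with
decreasing costs the bound rises first and collapses to $0.5$ at the
deadline.  Higher difficulty and higher uncertainty lower the bound's
overall height.

## Static criteria and their evaluation

A static policy uses a time-invariant threshold $\delta$ on the posterior:
decide left at $\pi \ge \delta$, right at $\pi \le 1 - \delta$, otherwise
wait; a trial that never crosses times out at $-1000$.  The threshold
$\delta = 0.5$ is admitted as the immediate-guess policy — without it the
static family could not express guessing, which the deadline-forced
dynamic policy can always do, and the static/dynamic comparison at extreme
difficulty would be distorted.  The asymmetry that the *dynamic* policy may
guess at the deadline while the *static* policy never does is deliberate:
it is what makes a high static bound incur certain loss near the deadline.

Policies are evaluated two ways, and the two routes are tested against
each other:

* **Exact forward propagation** pushes state-occupancy mass through the
  lattice under the *true* generative process, conditioning on each target
  side with probability $1/2$, and accumulates reward, cost, stopping time,
  accuracy, error, and timeout mass.  Under uncertainty the observations
  are still generated from the true rates; only the observer's updating
  marginalises — that is what "uncertainty about the rates" means
  operationally.  Mass conservation is checked to `1e-10` at every step.
* **Monte Carlo simulation** samples whole trials in fixed-size,
  counter-seeded batches until a quota of error trials (20,000 by default)
  has accumulated, so decision-time distributions are resolved even for
  accurate policies; it reports standard errors and reproduces identical
  trial streams for identical seeds.

For known rates the reachable posteriors form a small finite set, so the
candidate thresholds (0.5 plus the midpoints between consecutive reachable
posterior values) enumerate *every* distinct static policy and the
best-static search is exact, not a grid approximation; under uncertainty a
0.005-step grid on $\pi$ is used.  Ties go to the lower threshold.

## Sweeping the difficulty space

`make_grid()` lays a deterministic quasi-uniform design over the feasible
region of discriminating-event probabilities,
$\{\,0 < q < p < (1-\sqrt q)^2\,\}$: a Halton low-discrepancy sequence
(bases 2 and 3) mapped onto the bounding box $q \in (0, \tfrac14)$,
$p \in (0,1)$ and filtered to the region.  The published analysis shows its
201 sampled difficulty points only as dots in a figure, so their exact
positions are not recoverable; a low-discrepancy design was chosen because
it is reproducible, fills the region evenly at any requested size, and
makes sweeps deterministic.  `run_sweep()` then derives the optimal
dynamic policy, searches the best static threshold, evaluates both exactly
(Monte Carlo is available for fidelity checks), and `coverage()` reports
the fraction of points whose static/dynamic net-reward ratio reaches a
cut-off (0.95 by default).

Problem sizes used by the shipped tests and the acceptance script: a
51-point grid (the accepted reduction of the 201-point original) crossed
with both cost directions and $K \in \{1000, 100\}$, exact evaluation
throughout, and oracle comparisons at horizons $T \le 4$ where the full
$4^T$ history tree is enumerable.  The error-trial quota is reduced from
20,000 to 2,000 in the simulation-versus-exact agreement check; with exact
evaluation carrying the headline numbers, the quota only affects the
standard error of the cross-check.

## Known limitations

* **Coverage depends on the grid layout.**  The fraction of difficulty
  space where a static bound keeps ≥95% of the optimal reward rate is a
  property of the *design*, not only of the model: on a quasi-uniform
  grid the sub-0.95 band (moderate-to-high difficulty under increasing
  costs) occupies a larger share of the region than layouts that
  concentrate points near the easy outer boundary $\sqrt p + \sqrt q = 1$
  (as, for instance, designs uniform in the rates $(\theta_T, \theta_D)$
  do).  Decreasing-cost coverage is robust to the layout; increasing-cost
  coverage is not, and readers comparing coverage figures across studies
  should check the underlying design first.
* **Finite-`K` dominance is approximate.**  With uncertain rates the
  "optimal" dynamic policy is optimal under the observer's marginal
  predictive, while the best static threshold is selected by evaluation
  under the true process, so the static policy can very occasionally edge
  it out (relative margins $\sim 10^{-5}$ at $K = 100$ in our sweeps).  At
  $K = \infty$ dominance is a theorem and holds to `1e-9` everywhere.
* **What the simulator does not emulate.**  Trials are idealised Bernoulli
  streams processed by an exact Bayesian observer with a deterministic
  stopping rule.  Real observers show lapses, sequential dependencies,
  motor and non-decision time, and learning across trials; none of these
  are modelled, so passing tests certify the normative benchmark, not
  human behaviour.  Priors reset every trial (`K` is a fixed uncertainty
  level, not a learning state), mixed-difficulty environments are out of
  scope, and time is strictly discrete — there is no diffusion
  approximation.

## A compact example

```{r example, eval = FALSE}
env <- environment_spec(rate_pair(0.38, 0.24))   # the reference difficulty
pol <- backward_induction(env)                   # optimal dynamic bound
curve <- extract_criterion(pol)                  # delta_l(t), collapses to 0.5
dyn <- evaluate_exact(pol, env)                  # expected net reward
bs <- best_static(env)                           # exact best static threshold
bs$result$net_reward / dyn$net_reward            # static/dynamic ratio
```
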