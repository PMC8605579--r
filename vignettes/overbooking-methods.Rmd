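---
title: "Overbooking with set-resource constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overbooking with set-resource constraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overbookr)
```

## The problem

A physical examination center sells bundled examination **sets** (a basic
check plus colonoscopy, an MRI package, ...) but its capacity lives on
shared **resources**: the gastroenteroscope, the MRI machine, the DWI
add-on, and so on. Booking limits are decided per set; overtime and
crowding costs accrue per resource. The two sides are linked by a binary
set-resource matrix $V$, with $V_{ij} = 1$ when set $j$ consumes resource
$i$. Late cancellations — cancellations within seven days of the
examination, including plain no-shows — leave slots empty that cannot be
refilled, so the center considers overbooking: raising the per-set booking
limits $N_j$ above what the ideal resource capacities $K_i$ would allow if
everyone showed up.

If $x_j$ consumers show up for set $j$, resource $i$'s *overage level* is
$\max\{\sum_j V_{ij} x_j - K_i,\, 0\}$, and the realized *net reward* is

$$\pi(x) = \sum_j x_j P_j \;-\; \sum_i f_i\Big(\sum_j V_{ij} x_j - K_i\Big),$$

where $P_j$ is the set price and $f_i$ an increasing, convex overage cost
with $f_i(z) = 0$ for $z \le 0$. The center chooses booking limits
$N = (N_1, \dots, N_m)$ to maximize $E[\pi]$ over the feasible region
$S = \{N : \sum_j V_{ij} N_j \le K_i + U_i\ \forall i\}$, where $U_i$ is
the largest overage the center will ever tolerate on resource $i$
(`search_space()`, `is_feasible()`, `enumerate_search_space()`).

Three policies are compared throughout: **NO** (no overbooking,
$U_i = 0$), **OU** (overbooking with one uniform late-cancellation rate)
and **OC** (overbooking with cluster-specific rates).

## Overage costs

The cost schedule is elicited marginally: in the default configuration the
first three overage units cost 2,500 NTD each, the next three 5,000, the
next three 10,000, and the tenth 20,000, so for instance five units cost
$3 \times 2{,}500 + 2 \times 5{,}000 = 17{,}500$ NTD. Beyond ten units
elicitation is unreliable, so a zero-intercept quadratic
$y = a z + b z^2$ is least-squares fitted to the ten cumulative points and
used for $z > 10$ (`fit_extrapolation()`, `overage_cost()`):

```{r cost}
sched <- cost_schedule()
round(sched$coefficients, 3)
overage_cost(c(5, 10, 11, 12), sched)
```

Two numerical choices are deliberate. First, the table is authoritative up
to ten units and the curve is used strictly beyond it, even though the two
disagree at $z = 10$ (72,500 versus ≈ 68,461): the curve exists only to
extend the schedule, and smoothing the seam would change elicited values.
Second, extrapolated costs are rounded to whole NTD. Note the curve gives
82,817 NTD at $z = 11$; a published figure of 82,871 for the same quantity
appears to be a transposition, and the package follows the curve.
Sensitivity analyses scale the marginal table by a common multiplier and
refit the curve (`scale_schedule()`), which scales costs essentially
linearly.

## Show-up distributions

With per-slot late-cancellation probabilities $r_1, \dots, r_N$, the
show-up count is a sum of independent non-identical Bernoulli variables —
a Poisson-binomial variable. `exact_showup_pmf()` computes its pmf by the
standard $O(N^2)$ dynamic-programming recurrence, mathematically identical
to enumerating all $\binom{N}{x}$ show-up subsets. The exact route is used
everywhere in practice; `monte_carlo_showup_pmf()` implements the
simulation estimator (one uniform per booking per iteration, batch-wise
accumulation, stopping when the largest pmf change between successive
cumulative estimates falls below a tolerance) because convergence
behaviour is worth validating and because it generalizes to models where
exact computation is unavailable. Both are seeded and bit-reproducible.

## Estimating late-cancellation probabilities

The naive estimator is the overall proportion `uniform_rate()`. The finer
estimator proceeds in three stages (`fit_late_cancellation_model()`):
literature-motivated variables (age interval, gender, season, set) and
exploratory variables (group booking, last-minute booking, holiday
examination) are entered into a logistic regression of the
late-cancellation flag; insignificant variables (every level's Wald
$p \ge \alpha$, default $\alpha = 0.05$) are removed; remaining untested
variables are then offered and kept only if significant. Continuous
variables are factorized first — age into $[45, 70]$ versus outside, lead
time into $\le 7$ days versus longer, examination month into
winter/summer/off-peak — because the estimator downstream is a
cross-tabulation, not a regression surface. Variables can be
force-included: a borderline factor (e.g. holiday examination near
$p = 0.05$) is a judgement call that belongs to the analyst, not the
package.

Retained categorical factors are crossed into clusters
(`build_clusters()`), and each booking's probability $r_{jk}$ is its
cluster's empirical late-cancellation proportion
(`estimate_probability()`). Factors whose minority level has fewer than
`min_count = 100` records are excluded from clustering first: a
47-booking level would make its cluster rates noise. With the default
factors this gives $2 \times 3 \times 2 = 12$ clusters; empty clusters
fall back to the uniform rate. By construction the booking-weighted mean
of cluster rates equals the uniform rate.

The season grouping is configurable (`default_season_map()`), and
`compare_month_groupings()` refits the *full* offered model under each
candidate grouping and reports deviance and AIC; comparing pruned models
would let different groupings collapse onto the same final model. Deviance
is the criterion because the candidates are non-nested models of the same
data with equal parameter counts.

## Optimization

`expected_net_reward()` evaluates $E[\pi]$ exactly. The default method
exploits that the objective decomposes: revenue is linear in the per-set
expected show-ups, and the overage cost is separable per resource, so each
resource's cost expectation needs only the pmf of its load — the
convolution of the show-up pmfs of the sets using it. A literal
joint-support summation (`method = "joint"`, capped at $10^7$ states) is
kept as the textbook definition and as an independent oracle in the tests;
the two agree to floating-point precision. The sum runs over
$x_j = 0, \dots, N_j$: zero show-ups contribute no revenue but their
probability mass still weights the cost terms.

Under OC, hypothetical future bookings must be assigned cluster rates
before any are observed. `slot_probabilities()` apportions each set's $N_j$
slots to the season's clusters in proportion to within-cluster booking
shares using largest-remainder rounding with ties broken by cluster order,
making the optimization deterministic.

`complete_search()` evaluates every feasible combination (the default
case-study OU region has 15,466) and returns the maximizer, breaking ties
toward the lexicographically smallest combination; the full evaluation
list is retained for Pareto analysis. `greedy_search()` starts from the
all-zero combination (optionally from the center's original limits — both
conventions appear in practice) and repeatedly takes the unit increment
with the highest expected net reward, stopping when no feasible increment
improves the objective; it may stall at a local optimum, so it reports the
gap to a complete-search result when one is supplied.

## Simulation and policy comparison

`simulate_weeks()` evaluates a policy's limits under realized uncertainty:
each operating day every slot is booked (saturated demand — the observed
regime for the motivating center; a truncated-Poisson stochastic-demand
mode exists for robustness studies), each booking draws a cluster from the
season's mix and cancels late with that cluster's rate, and daily
revenue, per-resource overage and cost aggregate into weekly net rewards.
All three policies are evaluated under the *cluster* rates — the best
available stand-in for the truth — even though NO and OU chose their
limits assuming a uniform rate. Weekly rewards are compared with
`compare_policies()` (one-way ANOVA + Tukey HSD). `days_per_week`
defaults to 5 and is prominently configurable; absolute weekly magnitudes
therefore depend on two quantities (per-set prices, operating days) that
were never published for the motivating center, and the package treats
only directions and structure — not weekly NTD magnitudes — as
reproducible.

`sensitivity_analysis()` answers two distinct questions: *reoptimize* mode
re-runs the search under scaled costs (how should limits move if overage
truly costs more), and *underestimate* mode keeps the baseline limits
while charging the scaled costs (what does cost underestimation forfeit).
`pareto_frontier()` reports the non-dominated reward/overage-percentage
combinations among all evaluated ones, and the best combination under a
maximum allowable expected overage percentage; the overage percentage of
a combination is its expected total overage divided by expected consumers
served.

## The synthetic generator

The raw case-study records are private, so `generate_bookings()` emits a
synthetic population with the structure the analysis assumes: exactly the
12 published cluster sizes (8,046 bookings) with ages, examination months
and group sizes that re-derive into the intended clusters; late
cancellations drawn at the published per-cluster rates, shifted on the
logit scale by two rare flags — holiday examinations (rate 0.01, logit
effect 0.5702) and last-minute bookings (rate 47/8046, logit effect
2.0522); gender generated as pure noise; set choice from the published
aggregate-set mix (38.1/43.7/8.1/10.1%). The holiday frequency is set so
that holiday bookings are, as in the study, too rare to survive the
clustering `min_count` rule. Per-set prices are synthetic placeholders
(25,000/28,000/60,000/85,000 NTD) inside the published 20,000–100,000
range, as are the original booking limits (2, 22, 3, 3); no reproduced
quantity depends on either.

What the generator does **not** emulate: within-group correlated
cancellations (members of a group booking are modelled independently,
matching the estimation model's own independence assumption), weekday or
intra-day structure, consumer identity across bookings, and demand
shortfalls. Tests passing on this population therefore validate the
machinery and the published desk-scale numbers, not behavioural claims
about any real center.

## Problem sizes and determinism

The shipped configuration is the four-aggregate-set, five-resource case
study, with capacities $K = (36, 36, 24, 4, 2)$ and $U = K/2 =
(18, 18, 12, 2, 1)$, giving feasible regions of 3,900 (NO) and 15,466
(OU/OC) combinations — complete search evaluates each in milliseconds via
the convolution decomposition. Test simulations use 50 weeks of 5 days;
optimizer cross-checks use randomized instances with up to 3 sets and
limits up to 5, where joint enumeration is cheap. Every stochastic
routine takes an explicit seed; identical seeds give bit-identical
results.

## Known limitations

- Cluster rates are plug-in point estimates; their sampling error is not
  propagated into the optimization.
- The saturated-demand default overstates revenue for centers that do not
  fill their books; use the stochastic-demand mode.
- The overage cost is charged per day independently; fatigue or spillover
  across days is out of scope, as is intra-day slot scheduling.
- Group bookings cancel independently per member, which understates the
  variance of show-up counts when groups truly cancel together.
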