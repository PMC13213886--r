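---
title: "Dose finding with feasibility and late-onset toxicity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose finding with feasibility and late-onset toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtdc)
```

## The problem

Phase I trials of drug combinations that include a manufactured cell-therapy
product face three entangled complications that the classic single-agent
paradigm does not handle:

1. **Dose feasibility.** The cell product is expanded from the patient's own
   cells; manufacture may fall short of the assigned cell dose, so a patient
   may only be treatable at a lower combination — or at none at all. Throwing
   that patient's safety data away biases the dose-escalation.
2. **Partially known toxicity ordering.** When both agents escalate, two
   combinations that trade one agent's level against the other's cannot be
   ranked by DLT probability a priori. Only a partial order is known.
3. **Late-onset DLTs.** With a long observation window (here 10 weeks),
   waiting for every outcome before each escalation decision would stall
   accrual; ignoring pending patients wastes information.

`fmtdc` implements a design that addresses all three at once and targets the
*feasible maximum tolerated dose combination* (FMTDC): the dose with
estimated DLT probability closest to the target rate among doses that are
simultaneously safe and manufacturable for the patient population.

## Toxicity model

For dose combinations $j = 1, \dots, J$ and candidate simple orders
$m = 1, \dots, M$, the DLT probability is a one-parameter probit model

$$p_{j,m}(\beta) = \Phi\{\beta + \Phi^{-1}(q_{j,m})\},$$

where the skeleton values $q_{j,m}$ rearrange a single increasing skeleton
vector according to each candidate order: the dose in position $r$ of order
$m$ receives the $r$-th skeleton value. At $\beta = 0$ the model reproduces
the skeleton; $\beta$ shifts the whole dose-toxicity curve on the probit
scale, so within any order the estimated probabilities always preserve the
skeleton's ranking (the link is monotone in $q$ for every $\beta$, and
posterior averaging preserves pointwise order).

Pending outcomes enter through time-to-event weights. A patient observed for
$t$ of the $T$-week window without a DLT contributes
$\{1 - w\,p_{j,m}(\beta)\}$ with the linear weight $w = t/T$; a patient with
a DLT, or with a complete window, contributes with $w = 1$ (a DLT meets the
study endpoint and is fully observed). The weighted likelihood is

$$L_{t,m}(\beta) = \prod_i \{w_i\,p_{j_i,m}(\beta)\}^{y_i}
  \{1 - w_i\,p_{j_i,m}(\beta)\}^{1-y_i}.$$

Each candidate order carries a prior weight $\omega(m)$ (uniform by
default). At every decision the posterior order weights

$$\omega(m \mid \text{data}) \propto \omega(m)\int L_{t,m}(\beta)\,
  f(\beta)\,d\beta,$$

with $f$ a Normal$(0, \sigma^2)$ prior on $\beta$, select the working order
(largest weight, exact ties broken uniformly at random). Under the working
order, per-dose estimates $\hat p_{j,m}$ are posterior means of
$p_{j,m}(\beta)$; the estimated MTDC minimizes
$|\hat p_{j,m} - \theta^*|$ (ties to the lower dose index, the conservative
choice), and the safe set collects every dose whose estimate does not exceed
the MTDC's.

The toxicity stopping rule halts the trial when even the lowest dose is
likely too toxic:
$P\{\beta > \Phi^{-1}(\theta^*) - \Phi^{-1}(q_1)\mid\text{data}\} > p_{u,t}$,
evaluated under the working order's posterior. $q_1$ is the lowest dose's
skeleton value; because the lowest dose opens every candidate order in the
shipped design, this quantity is order-invariant there. We use the working
order's posterior rather than a model-average across orders; with the
lowest dose shared by all orders the difference is negligible, and the
working-order posterior is the one every other decision uses.

## Feasibility model

Cell doses are indexed $k = 1, \dots, K$; several combinations can share a
cell dose. Each expanded patient has an *individual highest feasible cell
dose* (IHFCD) in $\{0, 1, \dots, K\}$, where 0 means the product missed even
the lowest cell dose (the patient is excluded from treatment and from the
toxicity likelihood, but still counts as feasibility evidence). The IHFCD
counts $X = (X_0, \dots, X_K)$ are multinomial with a Dirichlet$(a)$ prior
on the category probabilities, so the tail probability
$\varphi_k = \pi_k + \cdots + \pi_K$ that a random patient can support cell
dose $k$ has the conjugate posterior

$$\varphi_k \mid X \sim \text{Beta}\Big(\textstyle\sum_{r \ge k}(a_r + X_r),\;
  \sum_{\ell < k}(a_\ell + X_\ell)\Big).$$

Cell dose $k$ counts as feasible while
$P(\varphi_k < \varphi^* \mid X) < p_{u,f}$; the *global highest feasible
cell dose* (GHFCD) is the largest feasible $k$, or 0 when none is. The
globally feasible dose set contains every combination whose cell count does
not exceed the GHFCD's; when it is empty the trial stops for insufficient
feasibility.

The Dirichlet prior defaults to the flat $a = (1, \dots, 1)$: equal prior
mass on each IHFCD category and a one-pseudo-patient-per-category weight, so
roughly three real observations already dominate it. Note a structural
consequence: with $K = 2$ the flat prior gives the top cell dose the prior
law Beta$(1, 2)$, whose CDF at $\varphi^* = 0.8$ is $0.96$, so the top cell
dose is *not* credibly feasible a priori (the prior GHFCD is 1). This is
harmless for conduct — patients are dosed by their own IHFCD, not by the
global set — but it explains why the global set typically starts at cell
dose 1 and grows only with data.

## Trial conduct

At each arrival the engine: (1) records the IHFCD; (2) if the IHFCD is 0,
excludes the patient and — under the default `feas_check = "each_failure"` —
re-evaluates the feasibility stop; (3) otherwise recomputes every treated
patient's weight at the current calendar time, checks the toxicity stop,
selects the working order, and (4) assigns a dose. Assignment treats at the
estimated MTDC when the patient's product supports its cell dose; otherwise
the patient receives, among the doses they can support whose position under
the working order does not exceed the MTDC's, the one with estimate closest
to the target. Because estimates are monotone along the working order, the
position condition is equivalent to "DLT probability not exceeding the
MTDC's". Escalation never skips: an assignment can be at most one position
beyond the highest position already tried under the working order. The
first treated patient always receives dose 1. Accrual ends at
`n_max` treated or `c_max` expanded patients, whichever comes first; the
final analysis completes all follow-ups (every weight 1), reselects the
order, re-checks feasibility, and picks the FMTDC from the intersection of
the safe and globally feasible sets — or reports 0 after any stop or an
empty intersection.

Two conduct details were genuinely open and deserve their rationale:

* **When to evaluate the feasibility stop.** The conduct algorithm tests the
  GHFCD at every manufacture failure, and that is the default. Users should
  know the flat prior makes this mid-trial test sensitive: the prior mean of
  $\varphi_1$ is $2/3$, already below the usual $\varphi^* = 0.8$, so two or
  three failures among the first handful of patients can push
  $P(\varphi_1 < \varphi^*)$ past $p_{u,f} = 0.9$ and stop a trial whose
  true feasibility is adequate. `feas_check = "final"` defers the decision
  to the final analysis, where thirty-odd expanded patients dominate the
  prior; with adequate true feasibility the two settings differ mainly in
  that early-failure false stops disappear.
* **Dosing below the assigned dose.** A patient whose product misses the
  MTDC's cell dose is still treated (at their best supportable dose) and
  enters the likelihood at the dose *received*. Discarding such patients is
  exactly the practice this design exists to avoid.

## The simulator

`scenario()` defines the synthetic-data generator: a true DLT probability
per combination and a true feasibility probability per cell dose (the
chance a random patient's product reaches at least that cell dose, a
non-increasing tail). The IHFCD multinomial is recovered by successive
differences of the tail — the minimal model consistent with one feasibility
number per cell dose. Arrivals follow a Poisson process (exponential gaps,
mean 4 weeks by default); DLT indicators are Bernoulli at the received
dose's true probability, and a patient destined for a DLT receives a
Uniform$(0, T)$ onset time, so outcomes genuinely straddle later decision
points. Each simulated trial runs on its own sub-seed drawn once from the
master seed, so operating characteristics replay exactly and independently
of batching.

What the generator does *not* emulate: patient dropout, non-uniform (e.g.
Weibull) onset times, accrual bursts or pauses, manufacturing covariates,
or feasibility that drifts over calendar time. Passing operating
characteristics therefore demonstrate the decision logic under the stated
stochastic model, not robustness to those real-world features.

`oc_scenarios()` bundles twelve benchmark scenarios for the shipped
four-dose design: six with monotone DLT curves (the first candidate order
correct) and the same six with doses 2 and 3 exchanged (the second order
correct), sharing the feasibility curves so the pairs are comparable.

## Numerical choices

All posterior quantities are one-dimensional integrals over $\beta$. They
are computed by fixed Gauss–Legendre quadrature (default 251 nodes) on
$\pm 8$ prior standard deviations, entirely in log space; the toxicity-stop
numerator uses a second node set on the tail interval so the indicator
introduces no discontinuity error. The node positions and the per-node dose
probabilities depend only on the design, so they are precomputed once
(`prepare_design()`) and each decision reduces to small matrix products —
this is what makes thousands of simulated trials cheap. The test suite
verifies agreement with 100,000-point Riemann sums to $10^{-6}$ relative
error on randomized datasets, and the Beta feasibility probabilities
against 200,000-draw Dirichlet Monte Carlo to $5\times 10^{-3}$.

Tie-breaking is deliberate: exact ties in the order posterior are broken
uniformly at random from the trial's seeded stream (so a fresh trial picks
its first working order at random), while ties in MTDC and FMTDC selection
go to the lower dose index. Degenerate inputs are validated up front
(`validate_config()` returns every violation rather than failing fast);
skeleton values must lie strictly inside $(0,1)$ so both link inversions
exist.

Default constants — target rate $\theta^* = 0.25$, feasibility threshold
$\varphi^* = 0.80$, stop cutoffs $p_{u,t} = p_{u,f} = 0.90$, caps 24
treated / 30 expanded, 10-week window, skeleton
$(0.13, 0.25, 0.41, 0.59)$, prior SD $0.74$ — are the motivating trial's
values and are all configuration inputs. Skeleton and prior-SD calibration
(indifference-interval and least-informative-prior constructions) are out
of scope: the vectors themselves are the inputs.

The test suite exercises the operating-characteristics study at 500
replicates per scenario, and the reproduction script
(`scripts/acceptance.R`) at 2000; at 2000 replicates the Monte-Carlo
standard error of a selection percentage is about one point.

## Known limitations

* One cell-therapy agent plus one partner agent; no three-way combinations.
* Simple orders must be supplied exhaustively; the package does not
  enumerate them from a partial-order description.
* Efficacy is not modelled; the design targets toxicity and feasibility
  only, and there is no cohort-expansion phase.
* The feasibility model treats manufacture outcomes as exchangeable across
  patients and constant over time.
* With a flat Dirichlet prior the mid-trial feasibility stop is
  conservative early in accrual (see above); trials worried about this
  should consider `feas_check = "final"` or a prior informed by platform
  manufacturing history.
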