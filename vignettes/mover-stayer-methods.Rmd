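---
title: "Trivariate mover-stayer counting-process models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trivariate mover-stayer counting-process models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moverstayer)
```

This vignette documents the model the package fits, the numerical choices
behind the implementation, what the simulator does and does not emulate,
and the design decisions taken where more than one reasonable choice
existed.

## The model

Damage in each joint area $k \in \{h, f, l\}$ (hands, feet, large joints;
capacities $T^k = 28, 20, 16$) is observed as cumulative counts
$N^k_{ij}$ at a patient's clinic visits $t_{i0} < \dots < t_{im_i}$. The
modelled quantities are the inter-visit increments
$D^k_{ij} = N^k_{i,j+1} - N^k_{ij}$, assumed conditionally independent
across intervals given the attained counts in all three areas — the
*dynamic covariates*.

**Mover component.** $D^k_{ij}$ follows a negative binomial distribution
with mean $\Lambda^k_{ij} = \Delta t_{ij}\, \lambda^k_0 \exp(\beta^{k\prime}
z_{ij})$ and dispersion $\theta^k \ge 0$, renormalised over
$\{0, \dots, T^k - n^k_{ij}\}$ (the remaining undamaged capacity). The
design vector $z_{ij}$ stacks any configured visit-level covariates (such
as active-joint counts) and the three attained damage counts, all
evaluated at the interval's **left endpoint**: values at visit $j$ predict
the increment to visit $j+1$, which is the only causally coherent choice
under intermittent observation. $\theta^k$ is a genuine parameter at 0:
the Poisson case is an exact branch, not a small-$\theta$ substitute,
because the truncated-Poisson variant (TM-SP) fixes all dispersions at
zero exactly.

**Pre-clinic damage.** The count present at clinic entry, accumulated
since arthritis onset, follows the same truncated negative binomial form
with mean $(t_{i0} - t^*_{i0})\lambda^{k0}_0$, dispersion $\theta^{k0}$,
truncated at the full capacity $T^k$. A zero onset-to-entry gap gives a
point mass at zero. These parameters are nuisance structure: their role
is to let the pre-clinic period inform the stayer proportions.

**Stayer component.** Conditional on a unit-mean frailty $U_i$ with
variance $\gamma$, patient $i$ is a stayer in area $k$ with probability
$\pi^k_{i1} = 1 - \exp(-u_i \omega^k_i)$, $\omega^k_i =
\exp(\alpha_1^{k\prime} z^\star_i)$. Marginally
$\pi^{k*}_1 = 1 - (1 + \gamma e^{\alpha})^{-1/\gamma}$, a link family
containing the logistic link at $\gamma = 1$ and complementary log-log as
$\gamma \to 0$ — so the data can choose between them. Stayer components
are intercept-only by default, matching how the marginal stayer
proportions are usually reported, but accept covariates.

**Marginal likelihood.** Writing $P_{ik}$ for the mover path probability
and $c^{*k}_i$ for the ever-damaged indicator, each never-damaged area
contributes $1 - e^{-u\omega}(1 - P)$ and each damaged area
$e^{-u\omega} P$. Expanding the product over areas in signs of
$e^{-u\omega}$ and taking expectations term-by-term reduces the frailty
integral to at most $2^{\#\text{never-damaged}} \le 8$ evaluations of the
frailty's Laplace transform. Both the gamma and the inverse-Gaussian
family are supported through the same Laplace-transform slot.

**Two-level extension.** To separate *true stayers* from *clinic-induced
stayers* (movers who become immune at clinic entry), a second binary
variable with its own frailty $V_i$ (independent of $U_i$) is layered
onto each area. Each area's conditional contribution falls into one of
three cases — never damaged; damaged only before entry
($n^k_{im_i} = n^k_{i0} \ne 0$); damaged in clinic — and each case is a
sum of at most three terms of the form $w\, e^{-u a \omega_1} e^{-v b
\omega_2}$ with $a, b \in \{0,1\}$. Independence of $U$ and $V$
factorises every one of the $\le 27$ signed product terms into
$\mathrm{LT}_U \times \mathrm{LT}_V$. This double expansion was derived
here by mechanically applying the same sign-expansion technique
area-by-area; its correctness is enforced in the test suite by agreement
with two-dimensional frailty quadrature to $10^{-6}$ relative error,
rather than trusted from the derivation. In every case the in-clinic
product runs over the *observed* increments, exactly as in the one-level
model (in the first two cases these are all zero); the enumeration
coherence test confirms the three cases exhaust the outcome space with
total probability one. The default family for $V_i$ is inverse Gaussian: its density
vanishes at 0, so a small clinic-induced stayer probability cannot be
mimicked by frailty realisations near zero, which is exactly the
identifiability failure a heavy-at-zero gamma density invites.

## Numerical choices

* All pmf arithmetic is on the log scale. The compiled kernel accumulates
  the truncation denominator through term ratios relative to $r = 0$
  (exact recursions, no log-gamma calls in the hot loop); a log-sum-exp
  fallback engages for extreme means or truncation bounds beyond 40,
  where the ratio terms could overflow.
* The signed expansion is accumulated in linear space. Its terms are
  bounded by 1 in magnitude and the sum is an expectation of a positive
  quantity, so linear accumulation is safe where pure log-space
  accumulation is impossible (alternating signs); the damaged-area
  product, which *can* underflow, stays in logs and is factored out.
* Patient contributions that still underflow are floored at $e^{-700}$
  with a warning, so optimisers see finite values.
* Intervals are deduplicated before fitting: the truncated log-pmf is
  evaluated once per unique (increment, spacing, design-row) tuple and
  scatter-added into per-patient path log-probabilities. On simulated
  data this cuts the dominant cost several-fold (stayers and
  damage-free movers share a single row).
* Zero-length intervals are rejected at validation — the increment
  distribution is undefined over zero exposure — with an opt-in merge of
  duplicate-date visits that keeps per-date maximum counts.
* Times are in years; intensities are per-year. Intervals come from the
  recorded visit dates and need not be equal.
* Working scale: log transforms for $\lambda_0, \lambda_0^{0}, \theta,
  \theta^{0}, \gamma, \psi$; identity for $\beta, \alpha$. Natural-scale
  intervals are the exponentiated working-scale Wald intervals, and
  derived stayer probabilities carry delta-method standard errors with
  intervals deliberately not truncated to $[0,1]$.
* Optimisation is BFGS with numerical gradients (relative convergence
  tolerance $10^{-10}$, 500 iterations). Starting values are data-driven:
  each area's baseline and regression coefficients are seeded by a
  Poisson regression of the increments on the design with a log-exposure
  offset among ever-damaged patients (a deliberately rough fit — it
  ignores truncation, dispersion and the stayer mixture — but it places
  the optimiser in the right basin, where zero-initialised coefficients
  occasionally converge to a spurious local maximum); stayer intercepts
  come from per-area damage-free fractions through the cloglog inverse;
  dispersions and frailty variances start at 1. A jittered multi-start
  option exists and is
  recommended for the two-level variant, whose second-level parameters
  are delicately identified. Non-convergence and boundary drift
  (|working parameter| > 30) are flagged on the result, not thrown.
* The observed information uses central second differences with relative
  step $10^{-4}$, symmetrised; inversion falls back to a pseudo-inverse
  with a warning when the condition number exceeds $10^{12}$.
* The truncation bound for in-clinic increments is the printed
  $T^k - n^k_{ij}$, so the pre-clinic count also consumes capacity.

## The simulator

`sim_design()`'s defaults are the reference generating conditions used by
the recovery study and the acceptance checks: 18 visits at 6-month
spacing; every patient enters the clinic at onset with no damage (the
pre-clinic model is then not applicable); no active-joint covariates;
gamma frailty with variance 3.9; stayer proportions 0.37/0.31/0.29;
baselines 0.37/0.61/0.14; dispersions 8/13/8; hand damage driving all
three intensities (0.10/0.08/0.03), foot damage its own area (0.04) and
large-joint damage the feet (0.10), all other cross-coefficients zero.
Increments are drawn from the exact truncated distribution by categorical
inversion, and all areas advance jointly each interval so the dynamic
covariates feed back correctly.

Each replicate of a study derives its seed as
$(\text{master} + 104729\,r) \bmod (2^{31}-1)$ and consumes one
sequential RNG stream (frailties, then mover indicators, then increments
interval-by-interval); studies run serially, so results are exactly
reproducible from the master seed alone.

What the simulator does **not** emulate about clinic data: irregular and
patient-specific visit spacing, missed visits and dropout, pre-clinic
damage at entry, active-joint dynamics correlated with damage, and
measurement/recording error in joint counts. Passing recovery tests
therefore demonstrate that the estimator recovers the generating
mechanism under the stated design — not that the model is correctly
specified for any particular cohort.

## Problem sizes in the checks

The test suite runs the recovery study at 30 replicates per sample-size
cell (100 at $n = 500$, where the same replicates also support the
SE-calibration and Wald-coverage checks), with replicate-mean estimates
compared to the reference study's means within three combined
Monte-Carlo standard errors; the standalone reproduction script uses
60/60/50 replicates at $n = 200/500/800$. The expansion-versus-quadrature equivalences use 200 random
one-level and 50 random two-level configurations; probability coherence
is enumerated exactly on capacity-2 toy designs. These sizes were chosen
so the whole suite runs comfortably on a single CPU while keeping every
Monte-Carlo comparison at the 3-sigma level.

## Known limitations

* Standard errors rely on inverting a finite-difference observed
  information; for near-boundary stayer parameters (e.g. a vanishing
  clinic-induced component) Wald theory is unreliable, and the profile
  likelihood tools are the honest diagnostic.
* No likelihood-ratio or score tests on the stayer boundary are offered:
  the mixture boundary makes their asymptotics non-standard.
* Model comparison is by reported log-likelihood and parameter counts
  only; no information criterion is endorsed.
* The rate at which movers *become* clinic-induced stayers over time is
  outside scope; immunity is modelled as acquired exactly at clinic
  entry.
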