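---
title: "Estimating the probability of being in response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the probability of being in response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrkit)
```

## The model

Response endpoints in randomized trials — response rate at a landmark,
best overall response (BOR), duration of response (DOR) — each capture one
facet of benefit. The probability of being in response, PBR(t), combines
them: it is the probability that a randomized patient occupies the
*in response* state at time t after randomization, under a progressive
three-state model:

* **state 0** — not (yet) in response, every patient's state at
  randomization (time 0, days);
* **state 1** — in response, entered at the first documented response;
* **state 2** — absorbing: response has permanently ended or can no longer
  be achieved. Once in state 2 a patient never leaves it, and the model
  allows no return from state 1 to state 0.

The transitions allowed are 0→1, 0→2 and 1→2. The event definitions follow
the conventions of chronic graft-versus-host disease trials: state 2 is
entered on death, start of new systemic therapy, relapse of the underlying
malignancy, loss of response (responders; "cGvHD progression"), or — for
never-responders only — failure to respond within the response window
(week 24 by default). A patient still under observation is censored in
whatever state they occupy.

Because every path visits state 1 at most once and in one block,
PBR(t) can be written through two ordinary survival functions:

* h(t) — probability of still being in state 0 at t (survival of
  `u_time`, the time of leaving state 0 by response or direct absorption);
* g(t) — probability of not yet being in state 2 at t (survival of
  `v_time`, the time of entering state 2).

Then `PBR(t) = g(t) − h(t)`. Both g and h are estimated by the
Kaplan–Meier product-limit estimator from right-censored data, so the PBR
estimate is a difference of two step functions on the union of their jump
grids. With no censoring it reduces exactly to the empirical fraction of
patients in state 1 at each t — the test suite checks this identity
bitwise against direct counting.

## Event derivation and the response window

`derive_multistate()` maps raw timelines (first response, terminal event
with a reason, last follow-up) to `(u_time, u_event, responded, v_time,
v_event)` with five mutually exclusive rules (responder censored in state 1
/ responder absorbed / direct 0→2 / window absorption / censored in
state 0). Choices worth knowing:

* **Week 24 = day 168** (24 × 7). Trials anchoring the window to a cycle
  calendar (e.g. Cycle 7 Day 1 = day 169 under 28-day cycles) can set
  `cutoff_days` accordingly; the package never hard-codes the convention.
* **A response recorded after the window is a validation error**, not a
  silent drop. The window rule changes the estimand; discarding data
  silently would hide upstream errors, so the caller must pre-truncate
  deliberately (`analysis_cutoff_days` exists for administrative
  truncation).
* **Same-day response and terminal event**: the response is applied first,
  so the patient passes through state 1 with zero duration. This keeps the
  latent ordering `u_time ≤ v_time` with equality allowed.
* **A never-responder's terminal event exactly on the window boundary**
  counts as a direct 0→2 transition (the recorded reason is more
  informative than the window rule); the boundary case is ambiguous and
  documented rather than hidden.
* Times are days as doubles; ties are permitted and resolved events-first,
  the standard product-limit convention.

Curves are **not cut at the window**: responses are only *counted* up to
week 24, but responders' follow-up and the estimated curves extend to the
end of observation.

## Confidence intervals

* Single-curve and difference **bands are pointwise percentile bootstrap**
  bands: subjects are resampled with replacement (arms independently for
  the difference), each replicate's curve is evaluated on the original jump
  grid, and the α/2 and 1−α/2 quantiles are taken per grid point. The
  default is `n_boot = 2000` and an explicit seed is required; identical
  seed and data give identical bands. A bootstrap was chosen because no
  published variance formula is being targeted, and subject-level
  resampling respects the coupling between the g and h curves. Negative
  values of g − h (possible in small samples because the two curves are
  estimated separately) are clipped to 0 with a warning; the raw difference
  is kept in the result.
* Kaplan–Meier **probabilities at fixed times** get complementary log-log
  intervals on the Greenwood variance — the common default in survival
  software and bounded inside [0, 1]. At S = 0 or 1 the interval collapses
  to the estimate (the Greenwood sum is undefined at 0; variance is
  reported as 0 there).
* **Medians** invert the pointwise log-log band (Brookmeyer–Crowley): the
  limits are the first times the respective confidence limit of S(t)
  reaches 0.5. The median itself is the smallest t with S(t) ≤ 0.5.

The expected duration of response `edor(fit, tau)` is the exact rectangle
sum of the PBR step function on [0, τ] — no quadrature — and equals, on
uncensored data, the mean per-patient time in response truncated at τ.

## The synthetic-trial generator and the closed-form oracle

Patient-level data from published trials of this design are not shareable,
so the package ships a generator that emulates the design: exponential
(Markov) transition intensities λ01, λ02, λ12, the response window, and
independent censoring (none, administrative at a day, or exponential).
Exponential rates were chosen because they give closed forms to verify the
estimator against; the sampling routine is isolated so piecewise-constant
rates could be added later. The closed-form occupation probabilities are

p0(t) = e^{−(λ01+λ02)t},
p1(t) = λ01 (e^{−λ12 t} − e^{−(λ01+λ02)t}) / ((λ01+λ02) − λ12)

for t up to the window close c, with the limit λ01 t e^{−λ12 t} when
λ01+λ02 = λ12 (the general branch is evaluated through `expm1`, so it is
stable arbitrarily close to the degenerate case); past c, the remaining
state-0 mass is absorbed (p0 = 0) and p1 decays as p1(c) e^{−λ12(t−c)}.
The closed-form expected duration of response is
(λ01/(λ01+λ02))/λ12 without a window and ∫₀ᶜ p1 + p1(c)/λ12 with one.

The default two-arm conditions — treatment λ01 = 0.022, λ02 = 0.004,
λ12 = 0.0012/day; control λ01 = 0.010, λ02 = 0.006, λ12 = 0.0025/day;
administrative censoring at day 500 — were fixed once to give a trial a
practitioner would recognize: median time to first response near 30 vs 50
days, BOR in the 60–90% range, and a control arm that both responds less
and loses response faster. They are conditions, not tuning knobs.

**Reproducibility protocol.** One root seed; each arm draws from a stream
seeded by a multiplicative mix of the root seed and the arm index, and
subject i consumes the i-th block of five uniforms. Enlarging `n_per_arm`
therefore appends subjects without reshuffling earlier ones, and nearby
root seeds give unrelated trials. (An earlier additive scheme made streams
overlap across nearby seeds, which visibly corrupted repeated-simulation
studies; the multiplicative mix removed this.)

What the generator does *not* emulate: visit-grid assessment (responses in
real trials are observed at scheduled visits, so observed response times
are interval-censored and cluster on the grid), covariate-dependent or
time-varying hazards, dependent censoring, and return transitions from
state 1 to state 0. Passing tests on this generator therefore validate the
estimator under the model's own assumptions, not robustness to their
violation.

## Verification

The test suite checks, among others: exact agreement of the PBR estimate
with direct state counting on uncensored data; hand-computed product-limit
values and Greenwood variances (cross-checked against the survival
package, which serves as an independent reference, never as the
implementation); sup-norm recovery of the closed-form p1 within 0.03 at
n = 5000 over one year (0.05 with administrative censoring at day 400);
the window rule in both the data and the h-curve; exactness and additivity
of the restricted area; 95% pointwise coverage of the difference band
(93–97% across 500 simulated 200-per-arm trials, 400 bootstrap replicates,
evaluated at day 50 — sizes chosen to make the Monte-Carlo study sharp yet
quick); and linear convergence of the general occupation formula to the
degenerate branch, with its extrapolated limit matching to 1e−8.

`scripts/acceptance.R` re-runs the default synthetic trial end to end
(arms of 165 and 164 patients, the rates above) and reports PBR at months
3/6/12, BOR, median time to first response, restricted EDoR at one year,
the day-91 difference with its band, and the large-n sup-norm error
against the closed form.

## Known limitations

* Pointwise bands only; no simultaneous confidence band and no global test
  of curve equality (a log-rank-type generalization for this estimand is
  an open problem).
* The estimator assumes independent censoring and no 1→0 transitions;
  relapsing–remitting response patterns need an extended model.
* Observed response times are taken at face value (no back-dating or
  interval-censoring adjustment).
* The naive cumulative-responder curve is provided for visual comparison
  only; it ignores loss of response and always lies at or above the PBR.
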