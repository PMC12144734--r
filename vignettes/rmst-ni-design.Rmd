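---
title: "Designing non-inferiority trials with treatment switching on the RMST scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing non-inferiority trials with treatment switching on the RMST scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmstni)
```

## The design problem

A non-inferiority (NI) trial asks whether a new treatment is *not
unacceptably worse* than an active control, usually because it is safer,
cheaper or more convenient. With time-to-event outcomes, the difference in
restricted mean survival times (DRMST),
$$\Delta(\tau) = R_2(\tau) - R_1(\tau), \qquad
  R_i(\tau) = \int_0^\tau S_i(t)\,dt,$$
is an attractive effect measure: it is the expected survival gain over the
first $\tau$ time units, it needs no proportional-hazards assumption, and it
is typically better powered than hazard-ratio comparisons. The test is
one-sided: non-inferiority is claimed at level $\alpha$ when
$$\hat\Delta(\tau) - z_{1-\alpha}\,\mathrm{SE}\bigl(\hat\Delta(\tau)\bigr)
  > -\delta,$$
with $\hat R_i(\tau)$ the area under the Kaplan–Meier curve and the standard
large-sample variance of the restricted mean.

The complication this package addresses is **treatment switching**
(crossover): in many oncology trials, control-arm participants may adopt the
experimental regimen after, say, disease progression. Intention-to-treat
analysis keeps them in the control arm, so the observed control arm is a
*mixture* of pure and partly treated participants with restricted mean
$R_1^*(\tau) \ne R_1(\tau)$. Testing against the margin $\delta$ chosen for
a switch-free trial then no longer controls the type-I error. The package's
remedy is the **adjusted margin**
$$\delta^* = R_1^*(\tau) - R_1(\tau) + \delta,$$
which makes the ITT test with switching decision-equivalent to the intended
switch-free test ($R_1^*(\tau) - \delta^* = R_1(\tau) - \delta$), while
$\delta$ retains its interpretation for the pure arms. When switching runs
the other way (experimental participants adopting the control regimen,
`TXswitch = "2to1"`), the mixed arm enters $\Delta$ with a positive sign and
the adjustment mirrors to $\delta^* = \delta + R_2(\tau) - R_2^*(\tau)$.

Power and sample size have no closed form in this setting, so both are
computed by Monte-Carlo simulation of complete trials.

## The generative model

**Event times.** Both arms follow generalized gamma distributions sharing
the shape parameters $b, k > 0$ and differing in scale:
$(T/a)^b \sim \mathrm{Gamma}(k)$. The family contains the exponential
($b = k = 1$), Weibull ($k = 1$) and gamma ($b = 1$) models, which covers
most shapes elicited in practice. Scales are calibrated from the median
survivals `m1`, `m2` through the exact inverse
$a = m / Q_k(0.5)^{1/b}$, so a design is stated in clinically meaningful
units (median survival) rather than distribution parameters.

**Accrual.** Participants enter over an accrual window $[0, T_a]$ with a
linear density — decreasing, uniform or increasing — and are followed until
the trial end $T_e$; the analysis clock is time since randomization, so
entry matters only through the administrative censoring horizon
$T_e - V$. `Ta = 0` puts everyone at the start.

**Censoring.** Given entry $v$, censoring mixes a dropout law (uniform on
$(0, u)$ or exponential) with an atom at the administrative horizon
$T_e - v$. Rather than asking users for the dropout parameter, the design
takes the *total censoring probability of the control arm under no
switching* (`censoring.prob`); the parameter is then solved by monotone
root-finding on that probability, evaluated by nested quadrature. The
administrative-only probability is the feasibility floor: a target below it
is rejected with both numbers in the message, a target equal to it degrades
gracefully to "no dropout". `censoring.prob = "AC.only"` skips dropout
entirely.

**Switching.** The switch time $S$ is modelled five ways, following the
catalogue used in simulation studies of crossover designs: three correlated
options $S = X T_1$ with $X \sim U(0,1)$, Beta or Gamma, an independent
exponential, and a fixed time (0 = switching at the trial start). The
correlated/independent laws are moment-matched to two interpretable inputs:
$r_s = E(S)/E(T_1)$, the mean switch time as a fraction of the mean event
time, and $\rho_s = \mathrm{corr}(S, T_1)$. The matching has a closed form:
$\mathrm{Var}(X) = r_s^2\,\mathrm{Var}(T_1)(1/\rho_s^2 - 1)/E(T_1^2)$ fixes
the Beta parameters via $a + b + 1 = r_s(1-r_s)/\mathrm{Var}(X)$ and the
Gamma rate via $b = r_s/\mathrm{Var}(X)$; solved parameters are verified
against the defining moment expressions at solve time. Two structural
constraints fall out of the algebra and are enforced with informative
errors: the uniform option forces $r_s = 1/2$ and its correlation is
structural (for exponential event times it equals
$0.5/\sqrt{5/12} \approx 0.7746$, which is where the package default
`rhos = 0.775` comes from), and the Beta option can only reach
$\rho_s$ above a law-dependent floor, which is reported when violated.

A participant *qualifies* for switching only when $S < T_1$ — the
counterfactual transform needs a positive remaining time — and then switches
with probability `ps` (an independent coin among qualifiers; the package
reads the switching probability as conditional on qualifying). Switchers
get the rank-preserving structural failure time (RPSFT) counterfactual
$$T_1^* = s + (T_1 - s)\cdot \mathrm{accel}, \qquad
  \mathrm{accel} = \mathit{af}\cdot m_2/m_1$$
(reciprocal for `"2to1"`): elapsed time is kept, residual time is stretched
by the relative effectiveness of the adopted regimen. `af` is a sensitivity
multiplier for the common-treatment-effect assumption; `accel = 1` is the
exact identity, implemented as such. Switching is decided on latent times
before censoring — a subject may "switch" after their censoring time, which
is harmless because the observed value is $\min(T^*, C)$ either way. For
`"2to1"` designs the switch-time law is moment-matched against the
experimental arm's own law ($S = X T_2$); the distinction is immaterial in
the fixed-time setting that motivates that direction.

**Allocation** is deterministic: exactly `n` control and `round(r * n)`
experimental participants (half away from zero — the reported expected
event counts are per fixed arm sizes, not per Bernoulli randomization).
Ties between event and censoring times count as events.

## Margins

Three constructions, resolved with the precedence *numeric margin*
$>$ *(`m0`, `f2`)* $>$ *`f1`*:

1. **Preserved fraction of the control RMST:**
   $\delta = (1 - f_1) R_1(\tau)$.
2. **Preserved fraction of the control-vs-placebo DRMST:**
   $\delta = (1 - f_2)(R_1(\tau) - R_0(\tau))$, with the hypothetical
   placebo calibrated from its median `m0` and sharing the shape
   parameters. $R_1 > R_0$ is enforced; $R_2 > R_0$ is checked against the
   configured alternative and reported as a warning, not enforced at test
   time, since the design's alternative is an assumption rather than data.
3. **Conversion from a hazard-ratio margin** $1/\theta > 1$ under
   proportional hazards:
   $\delta = R_1(\tau) - \int_0^\tau S_1(t)^{1/\theta}dt$.

When several options are supplied, an explicit numeric margin wins with a
warning naming what it overrode; `f1` alongside (`m0`, `f2`) is an error
unless the two resolve to the same number (within $10^{-9}$), because there
is no principled rank between them.

## Monte-Carlo machinery and numerical choices

* **RMST estimation.** The product-limit estimator and the standard
  large-sample variance
  $\sum_{t_i \le \tau} A_i^2\, d_i / \{n_i(n_i - d_i)\}$,
  $A_i = \int_{t_i}^\tau \hat S(u)du$, are implemented directly (they sit
  inside the innermost loop); the test suite verifies exact agreement with
  `survival::survfit` on censored data. Ties are events-first; a term with
  $n_i = d_i$ contributes zero. If the last observation precedes $\tau$ the
  curve is carried flat — deliberately, with a warning in the user-facing
  function: under increasing entry most follow-up ends before $\tau$ and
  this is precisely the regime where RMST estimation degrades (a slight
  type-I inflation there is a known property of the design, visible in the
  calibration studies, not an artifact to error out on).
* **Quadrature** uses adaptive integration with absolute tolerance
  $10^{-10}$; the exponential-dropout inner integral is computed after the
  substitution $w = e^{-\lambda u}$ so that large calibrated rates (a spike
  of dropout mass near 0) remain integrable.
* **Reproducibility.** One master `seed` spawns L'Ecuyer-CMRG substreams by
  counter, one per simulated trial; the margin-adjustment simulations use a
  dedicated block of substreams disjoint from the power-evaluation block,
  so $\delta^*$ and the power are estimated on independent randomness
  (re-using the same datasets would induce a small dependence bias).
  Identical design + seed gives bit-identical results; the caller's RNG
  state is restored afterwards.
* **Adjusted margin.** $R_1(\tau)$ and $\delta$ are analytic; $R_1^*(\tau)$
  is the average of `n_simulations` Kaplan–Meier RMST estimates of
  simulated mixed arms at the design's own arm size, so the adjustment
  inherits any finite-sample behaviour of the estimator it will be used
  with. `ps = 0` or `accel = 1` short-circuits to $\delta^* = \delta$
  exactly. A non-positive $\delta^*$ (switching shift exceeding the margin)
  is an error: such a design cannot be rescued by adjustment.
* **Type-I error studies** construct the null by handing the true gap
  $R_1(\tau) - R_2(\tau)$ to `margin`, so that the design's `m2` defines
  both the null and the switching benefit; `adjusted = FALSE` reproduces
  the inflation one is trying to avoid.

## Sample-size search

`calculate_size` evaluates the power at the $B + 1$ grid points
$n_L + j\,w$, $w = \mathrm{round}((n_U - n_L)/B)$, re-estimating
$\delta^*$ at every grid size, then fits a **monotone nondecreasing power
curve** and returns the smallest integer $n$ whose fitted power reaches
`epwr`. The smoother is a monotone-constrained penalized cubic regression
spline (`mgcv`: `smoothCon` + `mono.con` + `pcls`, smoothing parameter from
the unconstrained fit, fitted values clipped to $[0,1]$) — the standard
shape-constrained machinery in the installed toolchain; with fewer than
four points it falls back to isotonic regression with monotone
interpolation, with a warning. Grid evaluations use seeds `seed + j` so
points are independent; a fitted curve below `epwr` at $n_U$ is an error
advising a larger `nU`, and a curve already above `epwr` at $n_L$ returns
`nL` with a warning.

## What the generator does and does not emulate

The synthetic trials reproduce the features that drive NI power under
switching: staggered accrual, parametric event times, calibrated total
censoring, probabilistic switching with correlated switch times and a
common-treatment-effect counterfactual. They do **not** include covariates,
prognosis-dependent switching (switchers are exchangeable with
non-switchers given $S$), interim looks, or estimation of the acceleration
factor from data (the RPSFT model is used generatively only). Passing
designs therefore certify the procedure under the stated generative
assumptions — most importantly the common treatment effect, which `af`
exists to stress — not robustness to informative switching.

## Default parameters and problem sizes

Defaults mirror the conventional design surface: `r = 1`,
`shape = k = 1`, `ps = 0.2`, `rs = 0.5`, `rhos = 0.775`,
`s.dist = "gamma"`, uniform entry, `censoring.prob = "AC.only"`, uniform
dropout, `tau = Te`, `one.sided.alpha = 0.025`, `TXswitch = "1to2"`,
`af = 1`, `n_simulations = 5000`, `seed = 2024`. 5000 simulations put the
Monte-Carlo standard error of a power near 0.8 at about 0.006, small
against the 2% accuracy of the smoothed curve. The package's own
verification runs use 5000 simulations for single power and type-I-error
evaluations and 1500–5000 per grid point for size searches (the smoothing
borrows strength across the grid, so fewer replicates per point suffice);
those sizes are stated here as the package's reporting choice.

## Known limitations

* The adjusted margin controls the type-I error where RMST estimation
  itself is well behaved; under increasing entry with $\tau$ at the trial
  end, a residual inflation of up to about 0.005 remains (shortening
  $\tau$ resolves it).
* The margin adjustment is a location shift computed under the design
  parameters; it does not propagate uncertainty in $R_1^*$ into the test
  (its Monte-Carlo standard error is reported so users can judge it).
* Only two-arm designs and a single switching direction per design are
  supported.
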