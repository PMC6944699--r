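---
title: "Modeling the acquisition of temozolomide resistance through a transient persister state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the acquisition of temozolomide resistance through a transient persister state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persisterdyn)
```

## The scientific question

When a glioma cell line is driven to temozolomide (TMZ) resistance by
repeated dosing over roughly two weeks, two population-level mechanisms can
explain the observed dip-and-regrowth of viable cell counts:

* **Clonal selection** — a small resistant subpopulation (initial fraction
  $f_{R0}$) pre-exists and is selected by the drug;
* **Adaptive acquisition** — no resistant cells exist at the start; under
  drug, sensitive cells enter a *transient*, non-proliferating,
  death-protected persister state ("TR") and, after maturing in it, convert
  irreversibly into resistant cells.

Counts alone cannot separate the two. The discriminating observable is the
expression of the DNA-repair enzyme MGMT, reported as a bulk qPCR
fold-change over the untreated baseline: its *kinetics* — flat for days,
onset around day 9, plateau by day 16 — carry the signature of the hidden
population structure. `persisterdyn` implements both frameworks, the MGMT
observation model, least-squares fitting with practical-identifiability
analysis, AICc model discrimination, and a synthetic-data generator that
emulates the longitudinal experimental design, so the whole argument can be
run end to end in silico.

## Models

**Clonal selection.** With exposure $u(t) \in [0,1]$,
$$\frac{dS}{dt} = \rho_S S\,g(N) - \delta_S u(t) S, \qquad
  \frac{dR}{dt} = \rho_R R\,g(N) - \delta_R u(t) R,$$
with $S(0) = (1-f_{R0})N_0$, $R(0) = f_{R0} N_0$. Net proliferation and
baseline death are merged into $\rho$; the drug adds a death term gated by
$u$. $g(N) = 1$ by default — a 16-day passaged culture shows no saturation —
with a logistic $1 - N/K$ option.

**Adaptive acquisition.** The persister compartment is age-structured:
$n(t,a)$ is the density of transient cells of age $a$ (time since entry),
$$\frac{\partial n}{\partial t} + \frac{\partial n}{\partial a}
   = (\rho_{TR} - \mu_{TR} - \gamma(a))\,n, \qquad
  n(t,0) = \beta u(t) S(t),$$
$$\frac{dS}{dt} = \rho_S S - (\delta_S + \beta)u(t) S, \qquad
  \frac{dR}{dt} = \rho_R R - \delta_R u(t) R + \int_0^\infty \gamma(a) n\,da,$$
with $R(0) = 0$, $n(0,\cdot) = 0$, and a sharp maturation rate
$\gamma(a) = \gamma_{\max}\,[a \ge \tau]$ (a smooth Hill-shaped alternative
is available via `gamma_hill_n`). The defaults $\rho_{TR} = \mu_{TR} = 0$
encode the defining persister phenotype — no proliferation, no apoptosis;
$\rho_{TR}$ is left as a free knob because "slow growth" readings of the
transient state exist. Entry is drug-gated ($\beta u S$) by default, since
the transient population appears only under treatment;
`drug_gated_entry = FALSE` switches to constitutive entry.

**MGMT observation model.** The bulk fold-change of a mixed population is
the population-average per-cell expression
$$\mathrm{MGMT}(t) = \frac{S + c_{tr}\,TR + \alpha R}{S + TR + R},$$
with $\alpha \ge 1$ the resistant-to-sensitive per-cell expression ratio.
A "total expression" variant (numerator over a fixed baseline population)
is available behind `mode = "total"`; the default is the average, matching
bulk qPCR of equal RNA input. The `readout_params()` default is
$c_{tr} = 0$; the packaged *reference* scenarios instead use $c_{tr} = 1$,
because the observable is a fold-change over the untreated baseline and
persister cells express the same *basal* level as sensitive cells — the
MGMT-high phenotype belongs to the emerging resistant cells. With
$c_{tr} = 0$ the readout would dip far below 1 while the persister pool
dominates, which bulk fold-change data of this system do not show.

## Treatment schedules

`treatment_schedule()` maps dosing times to exposure. The canonical course
(`tmz_schedule(16)`) re-doses every 3 days with a 3-day full-effect window,
so exposure is effectively continuous at 1 for the treated interval; the
models consume this unitless effect, not a concentration (pharmacokinetics
are out of scope, but a per-dose exponential-decay mode exists for
sensitivity analyses). Dose metadata in µM lives only in labels.

## Numerics

* The clonal system with $g \equiv 1$ and window exposure is linear with
  piecewise-constant coefficients and is propagated *exactly* between
  exposure breakpoints. Other configurations integrate with `deSolve::lsoda`
  restarted at every breakpoint so discontinuities are never stepped over.
* The age-structured system is solved along characteristics with
  $\Delta t = \Delta a$ (default 0.05 d), which makes age transport exact
  (no numerical diffusion). Within each step, entry, conversion, death and
  proliferation are integrated in closed form under the step-frozen
  exposure; with all growth and death rates zero, pure transfer conserves
  $S + TR + R$ to machine precision by construction. The age domain is
  truncated at `a_max` (30 d) with an absorbing terminal bin that keeps
  converting at $\gamma_{\max}$. Empirical grid convergence is second
  order; fits use a coarser step (0.1 d, solution error $\sim 10^{-4}$ on
  log counts, far below the noise) for speed.
* Two independent oracles guard the solver: an agent-level stochastic
  simulation (exponential event clocks; per-cell deterministic maturation
  at exactly $\tau$ days after entry) whose ensemble mean must match the
  mean-field solution, and an Erlang-chain ("linear chain trick")
  approximation whose discrepancy must shrink monotonically in the number
  of stages. Neither is used for fitting.

## Fitting and identifiability

Residuals are $\log_{10}$ for counts (the dip/regrowth spans decades) and
$\log_2$ for MGMT fold-change (the qPCR-native scale); replicates enter as
independent rows; channel weights default to 1:1. Multi-start bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) is initialized by a seeded Latin
hypercube over the (log-scaled where flagged) bounds; the sorted result set
is a `fit_ensemble`, and fits within 5% of the best RSS form the *feasible*
set. `feasible_parameter_range()` reports the spread of a parameter over
that set — the practical-identifiability device — and
`profile_parameter()` complements it with an explicit RSS profile
(re-optimizing the other parameters at fixed values), which measures the
curvature of the loss rather than where converged starts happen to land.

A finding worth stating plainly: under the packaged study conditions
(observations at days 0/4/9/12/16, 3 replicates, 15% count CV, the 5%-RSS
feasibility threshold), the initial resistant fraction is *practically
identifiable from counts alone* — converged multi-start fits agree on
$f_{R0}$ to a few percent and the 5%-RSS profile band spans only about a
factor of 2. The famous order-of-magnitude spread of pre-existing-fraction
estimates arises only under a much more permissive notion of "fits the
data" (visually acceptable curves can sit at ~3x the optimal RSS). The
MGMT channel still tightens the estimate, and the ensemble/profile pair
makes the comparison explicit rather than anecdotal.

## Model discrimination

`compare_models()` fits both frameworks to the same channels and compares
small-sample-corrected AICc (appropriate for ~30 residuals); $|\Delta
\mathrm{AICc}| \ge 10$ is called decisive, anything less indeterminate.
The late-window ([12, 16] d) MGMT misfit of each best fit is reported
alongside, since the clonal framework's structural handicap — the MGMT
fraction and the count regrowth are locked to the same exponential
process, while the persister pool decouples them — is expressed late. On
counts alone the two frameworks are statistically indistinguishable here
(the verdict is indeterminate on ~95% of replicated synthetic studies),
which is exactly why the expression channel matters. With MGMT included
the adaptive model is preferred on adaptive-generated data with a median
$\Delta \mathrm{AICc}$ near the decisive threshold; because the threshold
sits in the middle of the $\Delta$ distribution under these noise levels,
the *decisive* verdict rate is closer to half than to certainty, and the
clonal best fit often tracks the mean MGMT sigmoid closely enough that its
late-window misfit is only modestly worse. Sharper discrimination would
need either more replicates, lower MGMT noise, or a larger expression
ratio than the reference $\alpha = 20$.

## The synthetic study and its reference parameters

`paperlike_scenarios()` packages six arms: the full 16-day course
(adaptive truth), the same design generated by the clonal model, treatment
stopped at day 3 or 6, a wash-out arm followed to day 28, and a TMZ +
persister-targeted-kill combination (the HDAC-inhibitor analogue). The
adaptive reference parameters were chosen once so the simulated experiment
reproduces the qualitative timeline of the real one — strong killing over
the first days, a persister-dominated plateau roughly days 4–12, MGMT
onset near day 9 rising to a plateau by day 16, regrowth after day 12:

| parameter | value | meaning |
|---|---|---|
| $\rho_S$ | 0.4 /d | net sensitive proliferation |
| $\delta_S$ | 1.2 /d | drug kill of sensitive cells at full exposure |
| $\beta$ | 0.35 /d | drug-gated entry into the transient state |
| $\tau$ | 8 d | maturation age |
| $\gamma_{\max}$ | 0.6 /d | conversion rate past maturity |
| $\rho_R$, $\delta_R$ | 0.5, 0.03 /d | resistant growth and residual kill |
| $N_0$ | $10^5$ cells | initial population (absolute scale is arbitrary) |
| $\alpha$ | 20 | MGMT expression ratio, resistant vs sensitive |

The clonal reference world shares $\rho_S$ and $N_0$, fixes
$f_{R0} = 0.4\%$ (the geometric center of the 0.02–6.97% range that
clonal-selection descriptions of such experiments admit), and takes
$\rho_R = 0.44$, $\delta_S = 0.50$ from a one-time least-squares match to
the noise-free adaptive curve, keeping the two in-silico worlds
observationally comparable.

Noise emulates the assay structure: mean-one lognormal multiplicative
noise on counts (CV 0.15 — scale-free across the dynamic range), additive
Gaussian noise on $\log_2$ MGMT (sd 0.25), 3 biological replicates, and a
100-cell detection floor. What the generator does *not* emulate — between-
replicate kinetic heterogeneity, day-to-day batch effects, assay-specific
censoring of MGMT near baseline — bounds what passing tests show about
real data: they validate the machinery and the in-silico argument, not the
biology of any particular cell line.

## The intervention experiment

`tsa_experiment()` contrasts three arms of the reference adaptive world
over 30 days of continued dosing: no intervention; a transient-state-
specific kill rate $\kappa$ (default 8 /d at full exposure) sustained from
day 3 — immediately after the persister pool forms; and the same kill
started only at day 16, after conversion. Early targeting keeps the final
resistant population below a single cell while the control regrows past
$N_0$; late targeting leaves the outcome within a fraction of a percent of
control. A bisection in the tests shows the minimal effective $\kappa$ is
far below the reference value — the timing, not the intensity, is what
matters.

## Problem sizes and design choices

Replicated experiments (recovery, identifiability, discrimination) use 20
seeded datasets; recovery fits use 12 starts (clonal) or 8 (adaptive),
discrimination 6 per model, identifiability 50 — sizes at which the
reported medians and fractions are stable under reseeding. The recovery
experiment for the adaptive model frees the mechanism parameters
($\beta, \tau, \gamma_{\max}$) with $\rho_R$ and $\alpha$, holding
$\delta_S$ fixed: the early-kill rate is directly measurable in such
experiments (death assays), while the persister mechanism is the unknown
of interest; leaving $\delta_S$ free mainly re-discovers its near-perfect
trade-off with $\beta$ in the first days. Model discrimination, by
contrast, gives both rivals the same five degrees of freedom including
$\delta_S$. Under effectively continuous exposure, only the differences
$\rho_S - \delta_S u$ and $\rho_R - \delta_R u$ are identifiable; the
bounded fits simply inherit that flat direction, which the ensembles
display honestly.

## Known limitations

* The exposure model is on/off per dose window; no pharmacokinetics, no
  dose–response calibration in µM.
* No spatial structure, microenvironment, immune compartment, or
  multi-clone genealogy within the resistant pool.
* The stochastic simulator freezes exposure between schedule breakpoints —
  exact for window schedules, approximate for decay schedules.
* MGMT expression is constant per state; an age-dependent expression in
  the transient compartment is stubbed (`c_tr`) but not resolved.
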