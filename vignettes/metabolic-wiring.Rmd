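---
title: "A metabolic scaling model for temperature-dependent development and brain wiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A metabolic scaling model for temperature-dependent development and brain wiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermowire)
```

## The model

Ectotherm development runs faster at higher temperature. `thermowire`
implements a metabolic account of what that does to neural circuits: if the
whole body and the brain are rate-limited by *different* metabolic
reactions, rearing temperature changes not just how long development takes
but the wiring outcome itself.

Ontogenetic growth follows the quarter-power law

$$\frac{dm}{dt} = a\,m^{3/4}\left[1 - \left(\frac{m}{M}\right)^{1/4}\right],$$

where $M$ is the asymptotic mass and the rate coefficient $a$ scales with
temperature as a Boltzmann factor $e^{-E/(K T_k)}$ of a rate-limiting
reaction with activation energy $E$ (eV), $K$ the Boltzmann constant in
eV/K and $T_k$ the absolute temperature. Expanding about the water freezing
point $T_a = 273$ K and writing $T$ for temperature in °C,

$$a(T) = a(T_a)\,
  \exp\!\left[\frac{E}{K T_a^2}\,\frac{T}{1 + T/T_a}\right]
  \approx a(T_a)\, e^{\frac{E}{K T_a^2} T},$$

which is `rate_factor()` in its `"exact"` and `"linearized"` modes. The
linearised form is the package default because the macroscopic scaling
factors are defined against it; the exact form exists to quantify the
approximation (the curvature term $T/T_a$ stays below $\approx 0.117$ up to
32&nbsp;°C, and `approximation_error_check()` measures the resulting error on
a fitted exponent — about 12% over the 12–31&nbsp;°C design, consistent with a
roughly-ten-percent figure).

Assuming eclosion at a temperature-independent mass, integrating the growth
law in the small-mass regime gives two closed-form fold changes relative to
a reference temperature $T_0 = 25$&nbsp;°C:

* developmental time: $t/t_0 = e^{-\alpha (T - T_0)}$ with
  $\alpha = E/(K T_a^2)$ (`devtime_fold_change()`);
* synaptic connectivity: $n/n_0 = e^{-\beta (T - T_0)}$ with
  $\beta = 4\,\Delta E/(K T_a^2)$, $\Delta E = E - E'$
  (`connectivity_fold_change()`),

where $E'$ is the activation energy limiting growth of the neural system
(axon extension, synaptogenesis), which is also assumed to obey a 3/4-power
law. The brain develops at its own pace but for a time set by ontogenesis:
if $E' < E$, colder-reared animals end up with *more* synaptic partners,
and at any matched fraction of ontogenesis the brain is in a more advanced
state by the same factor $e^{-\beta(T - T_0)}$
(`relative_brain_stage()` — the factor is independent of the fraction in the
small-mass regime, a property the test suite checks against the ODE
solver).

With the fitted factors $\alpha = 0.128$ and $\beta = 0.133$ per °C,
`activation_energies()` returns $E = 0.822$ eV and $E' = 0.61$ eV.

## Temperature cycles

For a two-level cycle spending half the period at $\bar T \pm \Delta T$,
integrating the growth law gives

$$\tilde t/\bar t = \frac{1}{\cosh(\alpha \Delta T)}, \qquad
  \tilde n/\bar n = \left[\frac{\cosh(\gamma \Delta T)}
  {\cosh(\alpha \Delta T)}\right]^4, \qquad \gamma = \alpha - \beta/4,$$

(`step_cycle_time_fold()`, `step_cycle_connectivity_fold()`). Because
$\gamma < \alpha$ whenever $\beta > 0$, fluctuations always yield fewer
connections than constant development at the mean temperature: development
is skewed toward the high-temperature phenotype.

`general_cycle_fold()` removes the step-change idealisation for arbitrary
piecewise-linear periodic waveforms, such as the experimental 8-h-hold /
4-h-ramp protocol (`trapezoid_profile()`). Development completes after many
cycles (about 20 cycles even for the fastest conditions), so the package
computes the many-period limit: fold changes built from the exact period
averages $\langle e^{\alpha T(\tau)}\rangle$ and
$\langle e^{\gamma T(\tau)}\rangle$. This limit is exactly phase-invariant,
reduces to the $\cosh$ laws on an equal-dwell square wave (the test suite
requires agreement to $10^{-6}$), and avoids the spurious
fractional-period edge effects a finite-horizon integration would add. The
period averages use composite trapezoid quadrature with 8000 points per
period and an internal doubled-resolution consistency check at $10^{-6}$;
a finite number of cycles below 20 only triggers a warning, since then the
averaging assumption itself is in doubt. The smooth ramps soften the
predictions relative to the square wave (ratios closer to 1) because less
time is spent at the extremes — both variants are provided since either
could underlie a plotted step-cycle prediction.

## Fitting the scaling factors

`fit_scaling_factor()` estimates $s$ in $\mathrm{fold} = e^{-s\Delta T}$
after `normalize_fold_changes()` divides every observation by the *mean*
value at the reference temperature (group mean, not per-individual
pairing). Choices that were genuinely open:

* **Loss.** Nonlinear least squares on the fold scale is the default
  (`method = "nls"`), with a log-linear regression as cross-check. The SSE
  profile in $s$ is one-dimensional, so the minimiser is a bracketed
  `optimize()` call on the exact loss — it agrees with `stats::nls` and a
  $10^{-4}$ grid search to $10^{-6}$ in the tests, converges
  unconditionally, and is fast enough to sit inside bootstrap loops.
* **Uncertainty.** Nonparametric bootstrap resampling individuals within
  temperature (default 1000 replicates, seeded). Each resample re-runs the
  whole pipeline *including normalisation*, so uncertainty in the
  reference-group mean propagates. The interval is a symmetric t-interval
  on the bootstrap SE with the small-sample inflation $\sqrt{n/(n-1)}$;
  plain percentile intervals undercover badly with very few individuals
  per temperature because the resampling distribution is then too
  short-tailed. Measured coverage is about 0.93 at the hemibrain-sized
  design and 0.85 with two individuals per temperature.
* **Recovery.** `recovery_experiment()` wraps the generator–fit loop and
  reports bias, RMSE and 95%-interval coverage. The acceptance suite runs
  200 replicates of the four-temperature design with 20–38 individuals per
  temperature and negative-binomial counts at $\beta = 0.133$.

## Connectome synapse allocation

`allocate_partners()` applies the synapse-table reduction in a fixed
order: drop pre→post connections with fewer than 3 synapses from a single
presynaptic neuron, sum per postsynaptic partner, drop partners below 10
total synapses, normalise, rank (descending count, ties by partner id).
The normalisation denominator is the total over synapses *surviving both
filters*, so retained fractions sum to 1 and are comparable across
glomeruli; the pre-filter total is available via `normalize = "prefilter"`
since the original wording is ambiguous on this point. Glomerulus
assignment (`assign_glomerulus()`) clusters raw 3D synapse coordinates with
k-means and 25 seeded restarts — no specific algorithm is canonical here,
and a centroid-based method suits compact, roughly isotropic glomeruli.
`estimate_report_threshold()` inverts an allocation against an observed
partner count to bound the detection threshold of a trans-synaptic
labeling method, and `innervation_symmetry()` is the signed left–right
volume index $100(V_L - V_R)/(2(V_L + V_R))$.

## Behavioral metrics

`odor_occupancy()` is the time-normalised trapezoid integral, over the
first 7 minutes, of the fraction of flies within 5 cm of the odor source
(1 when every fly spends the whole window there). `treadmill_response()`
computes per-trial speed change against a 3-s pre-stimulus basal over the
first 2 s of stimulation, excluding flies whose session-average basal is
below 2 mm/s. `fit_speed_modes()` decomposes pooled walking speed into the
zero peak (inactive flies) and a Gaussian
$a\,e^{-((x-b)/c)^2}$ fitted to the binned active mode, so $a$ tracks
activity level and $b$ the mean active speed. The inactive/active boundary
is not canonical; samples below 1 mm/s are assigned to the zero peak by
default (`active_cut`), and speeds come from central differences at the
native frame rate (20 fps).

## The synthetic-data generator

All inputs are generated in code (`generator_config()`,
`gen_partner_counts()`, `gen_devtimes()`, `gen_synapse_table()`,
`gen_trajectories()`), seeded and fully deterministic. The defaults are the
study conditions: rearing temperatures 12/18/25/31&nbsp;°C with tens of
individuals each, $\alpha = 0.128$, $\beta = 0.133$, negative-binomial
partner counts (dispersion 15 — counts of labeled cells across hemibrains
are overdispersed, though no specific distribution is implied by the data),
and lognormal developmental times (CV 0.08). The absolute scales at
25&nbsp;°C — 20 partners, 10 days — are placeholders, *not* measured values;
only fold changes matter to every downstream computation. Trajectories are
stop-and-go correlated random walks with a heading bias toward the source;
they emulate bimodal speed and odor approach but none of the fine structure
of real fly locomotion (saccades, wall-following, odor-plume dynamics), so
passing behavioral tests validates the metrics, not any claim about real
flies.

## Numerics and degenerate inputs

The growth ODE is integrated in the substituted variable
$u = (m/M)^{1/4}$, whose equation is linear and regular at $m = 0$ (the
mass equation has a degenerate equilibrium there, and the spec-level
initial condition is exactly $m_0 = 0$); `deSolve::lsoda` runs at
`rtol = 1e-8`, `atol = 1e-16`, and the closed-form solution serves as an
independent regression oracle at $10^{-6}$. Developmental completion is
time-to-target-mass with the small-mass regime operationalised as a target
of $10^{-3} M$. Degenerate inputs fail loudly and specifically: empty
synapse tables yield empty allocations (not errors), all-identical
coordinates cannot be clustered, a zero active mode cannot be fitted, and
recordings shorter than the occupancy window are rejected with the
required length in the message.

## Problem sizes

The test suite runs at desk scale: 200 recovery replicates with 1000
bootstrap resamples each for the coverage study, $10^4$–$10^5$ draws for
distributional checks, 30 flies × 40 minutes for the arena null, and
100 seeded datasets for the speed-mode recovery property. The full suite
completes in under two minutes on one core.

## Known limitations

* The exponential time law overestimates speed-up above ~30&nbsp;°C; no
  high-temperature saturation term is included, so predictions at 31–34
  °C inherit that bias (and observed developmental times on the most
  extreme cycles deviate accordingly).
* $\beta$ is circuit-specific; the packaged default describes one olfactory
  pathway and smaller values are plausible elsewhere.
* The step-cycle closed forms assume equal dwell at the two levels;
  asymmetric protocols must go through `general_cycle_fold()`.
* Partner-class percentages are lower bounds under incomplete annotation,
  and the allocation filters are threshold rules — they do not model
  reconstruction completeness.
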