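---
title: "Modelling and visualizing degenerate bursting neurons with burstscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and visualizing degenerate bursting neurons with burstscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstscape)
```

## Scope

`burstscape` is a toolbox for building and dissecting single-compartment
conductance-based models of bursting neurons of the crustacean
stomatogastric ganglion (STG). Neurons of this type are *degenerate*:
maximal conductance sets differing several-fold can produce nearly
identical membrane activity, yet respond very differently to perturbation.
The package provides the full chain needed to study this: a fast
Hodgkin–Huxley-type simulator with eight ionic currents and dynamic
intracellular calcium; threshold-based burst metrics; landscape (objective)
functions whose minima are bursting or tonic-spiking solutions, with a
seedable genetic algorithm to find them; *currentscapes*, a stacked-share
visualization of which current carries the membrane flux at each instant;
and probability-distribution "ridge maps" that display how the voltage
waveform and the current shares deform under graded conductance decrements
or injected current.

## The model

The membrane potential $V$ of a single compartment with capacitance $C$
obeys

$$C\,\frac{dV}{dt} \;=\; I_e \;-\; \sum_{i=1}^{8} I_i,
\qquad I_i = \bar g_i\, m_i^{p_i} h_i^{q_i}\,(V - E_i),$$

with currents ordered (Na, CaT, CaS, A, KCa, Kd, H, leak): a fast sodium
current, transient and slow calcium currents, a transient (A-type)
potassium current, a calcium-activated potassium current, a delayed
rectifier, a hyperpolarization-activated inward current, and an ohmic leak.
Currents are positive outward. Activation and inactivation gates relax to
voltage-dependent steady states,

$$\tau_{m,i}(V)\,\frac{dm_i}{dt} = m_{\infty,i}(V) - m_i,
\qquad
\tau_{h,i}(V)\,\frac{dh_i}{dt} = h_{\infty,i}(V) - h_i,$$

and intracellular calcium integrates the calcium currents with a
first-order buffer,

$$\tau_{Ca}\,\frac{d[\mathrm{Ca}]}{dt} =
  -\,C_F\,(I_{CaT} + I_{CaS}) \;-\; [\mathrm{Ca}] \;+\; \mathrm{Ca}_0 .$$

The state is 13-dimensional: $V$, eleven gating variables (four of the
currents carry an inactivation gate; KCa, Kd and H do not), and
$[\mathrm{Ca}]$. Units are fixed throughout as mV, ms, nA, µS, nF and µM,
which are mutually consistent (nF·mV/ms = µS·mV = nA).

Constants and their defaults (`stg_parameters()`): $C = 10$ nF,
$C_F = 0.94$ µM/nA, $\mathrm{Ca}_0 = 0.05$ µM, fixed reversals
$E_{Na} = 30$, $E_K = -80$, $E_H = -20$, $E_{leak} = -50$ mV. The calcium
reversal is dynamic, via the Nernst relation
$E_{Ca} = (RT/2F)\,\ln(\mathrm{Ca}_{out}/[\mathrm{Ca}])$ with
$\mathrm{Ca}_{out} = 3\times10^3$ µM. The temperature behind $RT/2F$ is
not pinned down by the sources this model family derives from; we default
to 12.2 mV ($\approx 10^\circ$C, the usual crustacean preparation
temperature) and expose it as `nernst_prefactor`.

### Gating kinetics

The kinetics of the seven voltage-gated currents are a *configuration*,
not code: `inst/extdata/kinetics_liu1998.yaml` holds, per channel, the gate
exponents $(p, q)$, the Boltzmann parameters of $m_\infty$ and $h_\infty$,
and one of three time-constant function forms (single sigmoid,
double-exponential denominator, or the two-factor product used by sodium
inactivation). The shipped values transcribe the lobster STG channel
models of Liu, Golowasch, Abbott & Marder (1998), themselves fitted to the
voltage-clamp measurements of Turrigiano et al. The KCa activation is the
voltage sigmoid multiplied by the saturation factor
$[\mathrm{Ca}]/([\mathrm{Ca}] + 3\,\mu M)$, so this current needs both
depolarization and accumulated calcium.

A caution that matters in practice: several renderings of this kinetics
table circulate in the literature, differing by factors of two in some
time constants (notably the sodium time constants and the calcium-current
inactivation time constants). The bursting waveforms of specific published
conductance sets are sensitive to these factors. We transcribed the table
as printed in the Liu-1998 lineage and verified the integrator itself to
$10^{-13}$ against an independently written reference integration, so any
residual disagreement with published waveforms for a given parameter row
traces to the kinetics rendering, not to the implementation. The
configuration file makes it trivial to swap in an alternative rendering.

## Numerical integration

`stg_simulate()` advances the 13-dimensional state with a fixed-step
classical Runge–Kutta (RK4) scheme, default `dt = 0.1` ms, from the fixed
initial condition $V = -51$ mV, all gates 0 (inactivation gates start
fully inactivated, as the configuration states them), $[\mathrm{Ca}] = 5$
µM. Adaptive or implicit schemes are deliberately out of scope: the
protocol this package reproduces is fixed-step RK4, and determinism
(bit-identical traces for identical inputs) is a design requirement.

Two evaluation modes exist for the gating functions:

* `method = "table"` (default): all $m_\infty$, $h_\infty$, $1/\tau$
  values are precomputed once per kinetics configuration on a 0.01 mV grid
  over $[-150, 100]$ mV and linearly interpolated. The interpolation error
  on a Boltzmann sigmoid at this grid is $\sim 10^{-6}$, far below the
  $O(dt^4)$ truncation error of the scheme; a test verifies that table and
  exact trajectories agree closely over hundreds of milliseconds. The
  table makes a 20 s simulation cost roughly 50 ms, which is what makes
  population-scale optimization practical on one core.
* `method = "exact"`: direct evaluation of the exponentials; used by the
  validation tests and available wherever bit-exact agreement with the
  closed-form rates is wanted.

The calcium-dependent factor of KCa and the Nernst reversal are always
evaluated exactly; only the pure voltage dependences are tabulated.
Non-finite states, $|V| > 1000$ mV, or non-positive calcium abort the run
with a typed error (`burstscape_integration_failure`) naming the failing
step; the optimization layer converts this to a penalty score instead of
crashing.

RK4 at `dt = 0.1` ms is stable for the shipped parameter rows but has no
safety margin to spare: reducing the capacitance (or otherwise speeding
the fast subsystem) below roughly half its physiological value makes the
scheme diverge, which the failure path is tested to report.

A caveat worth knowing: some conductance sets place the model in or near
chaotic regimes, where trajectories after tens of seconds are sensitive to
floating-point round-off at the level of instruction ordering. Burst
counts over a 10 s window for such rows are reproducible on one build of
the package but should not be expected to survive, say, a change of
compiler flags. The package's own tests only pin down quantities that are
robust to this.

## Trace metrics

All characterization is threshold-based (cheap, no spectral estimates):

* **Spikes** are upward crossings of $T_{sp} = -20$ mV: sample $n$ is a
  spike if $V_n \le T_{sp}$ and $V_{n+1} > T_{sp}$.
* **Bursts**: two spikes closer than $\delta_{spt} = 100$ ms belong to the
  same burst. For a burst with first/last spikes $s_i, s_k$ followed by
  another spike $s_{k+1}$, the duration is $\delta_b = s_k - s_i$, the
  period $\tau_b = \delta_b + (s_{k+1} - s_k)$, and one sample each of the
  burst frequency $f_b = 1/\tau_b$ and duty cycle $d_c = \delta_b/\tau_b$
  is collected. A lone spike is a burst of duration zero ($d_c = 0$),
  which is what lets the same machinery score tonic spiking. The first and
  last spikes of a trace are treated as having infinite-gap outer
  neighbours; the trailing burst yields no $(f_b, d_c)$ sample because its
  period is undefined, but it does count toward the number of bursts.
* **Slow wave**: downward crossings are counted at the threshold pair
  $-50 \pm 1$ mV; a clean burster crosses each threshold exactly once per
  cycle, so the summed count is twice the number of bursts.
* **Stability discard**: a trace is flagged unstable when
  $\mathrm{sd}(\{f_b\}) \ge 0.1\,\langle f_b \rangle$ or
  $\mathrm{sd}(\{d_c\}) \ge 0.2\,\langle d_c \rangle$, or when it has
  fewer than three spikes or fewer than two complete periods. Scored
  solutions are therefore stationary by construction.
* **ISI distributions**: first differences of the spike times. The number
  of *distinct* ISI values — the observable that turns an injected-current
  scan into a bifurcation diagram — is the number of single-linkage
  clusters at 2% relative tolerance, wide enough to absorb floating-point
  and discretization jitter yet far narrower than the spacing between the
  genuinely distinct ISI values of periodic regimes (doublets, quadruplets
  and the like differ by tens of percent).

## Landscape functions

`burster_target()` scores a conductance set by simulating 20 s, dropping
the first 10 s, measuring the trace, and combining

$$E_f = (f_{tg} - \langle f_b\rangle)^2,\quad
  E_{dc} = (d_{tg} - \langle d_c\rangle)^2,\quad
  E_{sw} = (\#sw/2 - \#b)^2$$

into $E(g) = \alpha E_f + \beta E_{dc} + \gamma E_{sw}$ with
$(\alpha,\beta,\gamma) = (1, 100, 1)$ and targets $f_{tg} = 1$ Hz,
$d_{tg} = 0.2$. $E_{sw}$ enforces the separation of spiking from slow-wave
activity: the membrane must dip below $-50\pm1$ mV exactly once per burst,
no more (spike troughs must stay above) and no less.

`tonic_target()` reuses the same segmentation with $d_{tg} = 0$ and adds
three terms: $E_{mid} = \sum_i (\#mid_i - \#s)^2$ over mid thresholds at
$-35, -40, -45$ mV (each must be crossed downward exactly once per spike,
penalizing slow-wave wiggles during repolarization), $E_{sw} = (\#sw)^2$
(a tonic spiker must never reach $-50\pm1$ mV), and a lag term $E_{lag}$,
the mean delay from each spike's upward crossing of $-20$ mV to the next
downward crossing of $-35$ mV, which separates true tonic spikers from
single-spike bursters with identical spike trains. Unpaired crossings
contribute the mean ISI as a cap; the weights are
$(\alpha,\beta,\gamma,\delta,\eta) = (1000, 1000, 100, 100, 1)$.

Discarded candidates — integration failures, near-silent cells, unstable
solutions — receive the fixed finite score $10^6$ so an optimizer can
still rank them below any behaving solution. $E$ is non-negative and zero
only when every term is zero; holding other terms fixed it is strictly
monotone in each mismatch, both of which are property-tested.

## The genetic algorithm

`ga_minimize()` is a standard generational GA over the 9-dimensional box
$\bar g_{Na} \in [0, 2000]$, $\bar g_{CaT}, \bar g_{CaS}, \bar g_A,
\bar g_{Kd}, \bar g_H \in [0, 200]$, $\bar g_{KCa} \in [0, 2000]$,
$\bar g_{leak} \in [0, 20]$ µS, $\tau_{Ca} \in [0, 1000]$ ms: uniform
random initialization, rank-based parent selection, uniform per-gene
crossover (probability 1/2), per-gene mutation by uniform resampling
within bounds at rate 5%, and elitist preservation of the best-ever
individual. Runs are exactly reproducible from the config seed.

The selection pressure knob deserves a note. The scheme is specified by a
single *elitism* parameter, 1.2 by convention, with 1 corresponding to
equal breeding probability. Two readings are possible: linear ranking in
which the best rank's breeding weight is 1.2× the population mean, or
geometric ranking in which each rank breeds 1.2× as often as the rank
below it. We implemented both and measured them on the bursting landscape
at reduced scale (population 100, 200 generations): under the linear
reading the best-to-worst pressure is only 1.5:1, some 98% of the
population still sits at the penalty score after 200 generations, and the
search stalls around $E \approx 3$; under the geometric reading the same
budget descends to $E \approx 1$. The package therefore uses geometric
rank weights. Two structural limits of the reduced scale are worth
knowing: a uniform random population of 100 typically contains *no*
scoring candidate at all (every one is discarded), so the early search is
pure drift until mutation stumbles on a burster — the published searches
used ten times the population; and because all discarded candidates share
one flat penalty score, that drift phase receives no gradient. Mutation by
uniform resampling also bounds the terminal accuracy on smooth objectives
— there is no creep operator — so convergence tests on analytic bowls
assert modest tolerances.

## Currentscapes

At every time step the currents are split by sign; the positive part
$C^+$ is normalized by the total outward current $n^+_j = \sum_i C^+_{ij}$
(and likewise the magnitudes of the negative part by the total inward
current), giving share matrices $\hat C^\pm$ whose columns sum to one
wherever the total is nonzero. Zero-total columns are flagged and render
as gaps. For display, each column is rasterized into $R = 2000$ pixel rows
(`build_cs_matrix()`): channel $k$ occupies the pixel rows between the
floored cumulative boundaries
$\lfloor R\sum_{m<k}\hat C_m\rfloor$ and $\lfloor R\sum_{m\le k}\hat
C_m\rfloor$, with the final band absorbing the rounding remainder so
unit-sum columns always fill exactly $R$ rows. Property tests check pixel
conservation (each channel within one pixel of $R\,\hat C_i$, total
exactly $R$), agreement of the band boundaries with an independent
cumulative-share computation, and reconstruction of the shares from band
heights to within $1/R$. The stacking order is the fixed channel order
(Na, CaT, CaS, A, KCa, Kd, H, leak) for both signs. `render_currentscape()`
draws the conventional stack — voltage trace, log-scale total-outward
envelope with dotted reference lines at 5, 50 and 500 nA, the two share
images, and the log-scale total-inward envelope.

## Distribution sweeps and ridge maps

Because the membrane potential spends most of its time where $dV/dt$ is
small, the histogram of $V$ sampled at random times concentrates at
waveform extrema: spike peaks, the slow-wave trough, plateau shoulders.
`sweep_distribution()` exploits this to compress an entire perturbation
series into one image: for each of a series of decrement levels (default
descending from 1, control, to 0, deletion) it rescales one maximal
conductance, simulates, and histograms either $V$ (1001 bins over
$(-70, 35)$ mV) or one current's share of the total inward or outward
current (1001 bins over $[0, 1]$). Per level, $2\times10^6$ time stamps
are drawn uniformly with replacement from the retained window (seeded;
using every sample instead is an option and differs only by sampling
noise). Bins are half-open with the last bin closed; out-of-range values
are clipped into the edge bins with a warning. Each row of the count
matrix sums exactly to the number of samples, which is asserted.

`ridge_map()` applies the display transform $\log_{10}(p + 1)$ and
differentiates it along the $V$ axis by central finite differences
(one-sided at the edges), per level row. Waveform extrema then appear as
zero crossings flanked by opposite signs — thin curves tracing, e.g., each
spike's amplitude across the whole decrement series. The closed-form
anchors used to validate the histogram machinery are the arcsine law for
sinusoids and the uniform law for sawtooth ramps, both matched to a
Kolmogorov–Smirnov distance below 0.01 at $2\times10^6$ samples.

## Perturbation drivers

`decrement_traces()` (graded scaling of one conductance),
`delete_channel()` (equivalent to level 0, tested as such), and
`injection_scan()` (ISI multisets on a grid of injected currents) all
restart every condition from the same fixed initial condition rather than
continuing from the previous level. The model family is multistable in
places, and continuation-style sweeps would entangle the observed
transitions with hysteresis; fresh starts make every level independently
reproducible. The cost is that a sweep can under-report coexisting
attractors that only continuation would visit.

## Problem sizes

Defaults are chosen for interactive, single-core use ("desk" profile):
scoring simulations of 20 s at `dt = 0.1` ms with a 10 s transient;
distribution runs of 30 s retained after a 30 s transient at `dt = 0.01`
ms; injected-current scans of 20 s per level on coarse grids. The
published analyses that these tools re-implement used substantially larger
sizes — 1001-level sweeps, `dt = 0.001` ms distribution runs after 120 s
transients, 580 s injection scans — available via
`stg_profile("published")` where a driver takes a profile, at proportionally
larger cost. The desk-scale defaults change sampling noise and transient
contamination, not the definitions of any quantity.

## What the tests do and do not establish

The test suite validates the numerics (RK4 order, bookkeeping between
$C\,dV/dt$ and the recorded currents, table-vs-exact agreement), the
segmentation and its brute-force oracle, the normalization and pixel
accounting of the visualizations, closed-form histogram laws, GA
determinism and monotonicity, and desk-scale reproduction of published
burster fingerprints (ISI cluster structure under current injection,
decrement transition locations, slow-wave separation). It does not
establish biological validity of the channel models themselves, and — per
the kinetics caution above — quantities tied to the exact burst shape of
specific published conductance rows (duty cycles, interburst intervals,
spikes per burst) depend on which rendering of the kinetics table the
original solutions were bred under; several such checks are expected to
disagree with their published values under the shipped rendering and are
kept in the suite as honest records of that sensitivity rather than
relaxed until they pass.

## Known limitations

* Single compartment, eight fixed current types; no networks, no
  multi-compartment morphology, no temperature dependence, no channel
  noise.
* Fixed-step RK4 only, by design; stiff parameter corners fail loudly
  rather than being integrated adaptively.
* The GA has no crowding or niching; it returns one solution per run, and
  breeding pools of diverse solutions is done by re-running with different
  seeds.
* Figure rendering targets base-graphics raster output; it is meant for
  inspection and regression testing, not publication typography.
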