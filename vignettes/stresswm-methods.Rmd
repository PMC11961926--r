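---
title: "Modeling stress effects on working memory: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stress effects on working memory: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stresswm)
```

This vignette explains the model `stresswm` implements, the choices that
were genuinely open when it was built, and what its tests do and do not
establish. It states no numbers that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The model

### Neurons

Each neuron is a two-compartment leaky integrate-and-fire unit. The somatic
membrane obeys

$$C_m \frac{dV}{dt} = -g_L\,(V - V_L) - I_{syn}(t),$$

with capacitance $C_m$ (pF), leak conductance $g_L$ (nS) and resting
potential $V_L$ (mV). The membrane equation itself carries no spike
mechanism, so threshold $V_{th}$, reset $V_{reset}$ and refractory period
$t_{ref}$ are explicit configuration parameters (defaults $-50$, $-60$ mV,
2 ms for excitatory and 1 ms for inhibitory neurons, in the style of
classical cortical attractor models). Every acceptance-level check either
is independent of these defaults or treats them as part of the configured
study condition.

### Synaptic currents and their sign

All receptor currents are driven by the common driving force $(V - V_L)$:

- recurrent NMDA: $\beta_{NMDA}\,\mu\,g\,(V-V_L)\,/\,(1+\gamma
  e^{-\beta V})\,\sum_j w_j s_j u_j$, with the magnesium-block constants
  $\gamma = 0.2801$, $\beta = 0.062\,\mathrm{mV}^{-1}$ (standard values;
  they are not fixed by the source equations, which leave the constants
  unnamed);
- recurrent AMPA: $\beta_{AMPA}\,\mu\,g\,(V-V_L)\sum_j w_j s_j u_j$;
- external AMPA: $g\,(V-V_L)\sum_j s_j^{ext}$ (no weights, no short-term
  plasticity; optional NMDA receptors on external input exist but are off
  by default);
- GABA: $\mu\,g\,(V-V_L)\sum_j s_j$. As defined, the inhibitory sum has no
  per-synapse weight; since the current is linear in $s$, the engine folds
  its connectivity weights into the gating vector, which is equivalent.

A consequence of the shared $(V-V_L)$ driving force is that *every* current
vanishes identically at $V = V_L$ — there is no synaptic drive at rest, and
excitatory input is regenerative above rest. The model therefore needs a
background somatic current `I_bg` to set a subthreshold operating point
above $V_L$; recurrent excitation then acts like a reduction of the
effective leak, inhibition like an increase of it (shunting toward $V_L$).
The signed combination is made in one place, `totalCurrent()`:

$$I_{total} = \beta_{NMDA} I_{NMDA} + I_{AMPA,ext} + \beta_{AMPA}
I_{AMPA,rec} - I_{GABA} + I_{soma,dend} + I_{bg},$$

with all components stored as depolarizing magnitudes and GABA subtracted.
Note that the total deliberately contains both the raw receptor currents
and the dendrite-to-soma transfer computed from those same currents; that
is the published form of the total and is implemented verbatim. The
$\beta$ factors appear both in the current definitions and in the total;
to avoid double scaling, the current functions default to $\beta = 1$ and
the engine applies the acute factors once, in the total.

### Dendrites

Dendritic excitatory current ($I_{NMDA} + I_{AMPA,ext} + I_{AMPA,rec} +
I_{bg}$) and inhibitory current ($I_{GABA}$) pass to the soma through a
saturating transfer

$$I_{soma,dend} = c_1 \tanh\!\left(\frac{I_{exc} + c_3 I_{inh} + c_4}
{c_5\, e^{-I_{inh}/c_6}}\right) + c_2 .$$

The printed form of this expression is ambiguous about bracket placement;
this reading (inhibition shifts the inversion point through $c_3$ and
rescales the gain through the exponential denominator) follows the cited
two-compartment literature, and the transfer is exposed as a pluggable
strategy (`transfer` argument of `runSimulation()`) so an alternative
reading can be substituted without touching the engine. Defaults
($c_1 = 30$, $c_2 = 14$, $c_3 = -1$, $c_4 = -50$, $c_5 = 100$,
$c_6 = 200$ pA) bound the dendritic contribution to a few tens of pA.

### Short-term plasticity

Excitatory terminals carry facilitation $u$ and depression $x$:

$$\frac{du}{dt} = \frac{U-u}{\tau_u} + U(1-u)\sum_k \delta(t-t_k), \qquad
\frac{dx}{dt} = \frac{1-x}{\tau_x} - u\,x \sum_k \delta(t-t_k),$$

with $U = 0.15$, $\tau_u = 1500$ ms, $\tau_x = 2$ ms. Between spikes the
package uses the exact exponential update (unconditionally stable,
identical to Euler as $dt \to 0$). The continuous-time jump terms are
simultaneous, so a discrete ordering had to be fixed: the "ux" convention —
$u$ jumps first, and the gating and resource updates use post-jump $u$ with
pre-drop $x$. Gating increments are $x u \gamma_{AMPA}$ for AMPA,
$x u (1-s) \gamma_{NMDA}$ for NMDA (saturating at 1) and a bare
$\gamma_I$ for GABA terminals. No state variable is ever clamped; the
bounds $U \le u \le 1$, $0 \le x \le 1$ hold by construction, and
$s_{NMDA} \le 1$ holds whenever $\gamma_{NMDA} \le 1$ — sweeping
$\gamma_{NMDA}$ above 1 can push $s_{NMDA}$ transiently above 1, which is a
property of the saturating-increment form itself, not an implementation
artifact.

### Spine counts and the chronic transform

Effective synapse-count multipliers derive from mean dendritic spine
counts. For excitatory neurons, NMDA and AMPA each get
$EXN\,(1-fac)\,(1-EXN\_IN)\cdot 0.5$ and GABA gets $EXN\,(1-fac)\,EXN\_IN$,
where $EXN\_IN$ is the inhibitory input fraction $i/(i+e)$; interneuron
multipliers combine bipolar and multipolar spine counts with the same
halved excitatory-share form for *all three* receptors — including GABA,
which is asymmetric with the excitatory-neuron GABA rule. That asymmetry
is implemented exactly as defined, deliberately not "corrected". Chronic
stress sets $fac = 0.16$ (16% spine loss), scaling every excitatory-neuron
multiplier by exactly 0.84 while leaving interneurons untouched; this is
asserted exactly in the tests.

### Stress conditions

Acute conditions are pure current scalings. The forced-swim preset uses
the measured EPSC amplitude ratios $\beta_{NMDA} = 425/197 \approx 2.157$
and $\beta_{AMPA} = 98.8/58.6 \approx 1.686$; the restraint and
elevated-platform presets are configurable placeholders (their published
amplitudes are not available here). The ketamine-style condition is
modeled generically as the chronic base plus an NMDA current-strength
increase. Chronic conditions recompute the spine-derived multipliers,
optionally rescale the per-neuron GABA increment factor
($\gamma_I$-scale), and optionally rescale within-group connection blocks
(EE, IE, EI, II).

## The network and its default regime

Four selective groups, each 40 excitatory + 10 inhibitory neurons by
default (200 total), Bernoulli block connectivity, within-group excitatory
coupling stronger than between-group coupling. Heterogeneous mode draws
positive parameters from truncated Gaussians with a 10% coefficient of
variation and membrane potentials with an absolute 2 mV jitter — a
relative cv on a quantity whose zero is arbitrary would be meaningless and
in practice produced neurons born at threshold. Homogeneous mode draws
uniformly within a ±10% band and makes no type distinctions. All
default connection probabilities, weights and spine counts are documented
stand-ins at realistic orders of magnitude: the in-vivo tables they
emulate are not available, so they are treated as replaceable data
(configuration), not code.

The default network sits deliberately in a *drive-limited* regime: between
group inhibition is comparatively weak (I→E weight 0.5, between-group
probability 0.15), so each group's ability to sustain delay activity is
governed by its own recurrent drive relative to threshold, graded by
heterogeneity. In this regime measured capacity increases with the
glutamatergic increment factors, decreases with the GABA increment factor
and increases with within-group E-E strength — the directions the sweep
tests assert. The alternative, competition-limited regime (strong
between-group inhibition) pins capacity at 1 regardless of overall drive,
because the increment factors scale E→E and E→I drive symmetrically while
$s_{NMDA}$ saturates and GABA gating does not; that regime demonstrates
winner-take-all but cannot show the strength-capacity trends. The shipped
`chronic_enhanced_EE` example configuration therefore carries its own
reinforced between-group inhibition (I→E weight 1.0, probability 0.25,
NMDA conductance 1.2 nS) together with chronic spine loss and threefold
within-group E-E coupling: two of the four groups win, sustained by their
strengthened mutual excitation, while the winners' interneurons silence
the rest. Both regimes are ordinary configurations of the same model.

## Protocol and inputs

Fixation 1000 ms, memory stimulus 400 ms, delay 1000 ms, cue 5 ms, post-cue
window 500 ms. All excitatory neurons receive independent Poisson drive at
the epoch's rate (default 900 Hz aggregate per neuron during memory and
cue, zero otherwise; the cue reuses the memory intensity). The default
rate was chosen once so that the control network sustains at least one
group through the delay. Stimulus-intensity gradients are expressed as an
optional linear ramp across the memory epoch (`ramp_start`), constant by
default. The engine draws the input as per-step binned Poisson counts,
which is distributionally identical to binning the spike-time lists
produced by `generatePoissonInput()`; the latter remains the user-facing
generator and is tested against a Poisson oracle.

## Numerics

Fixed-step forward Euler at `dt = 0.05` ms (configurable); gating and STP
decay use exact exponentials; synaptic transmission has a one-step delay;
spikes are stamped at the end of the crossing step. Euler convergence to
the analytic membrane solution is asserted at observed order 1. Non-finite
membrane values abort the run with the step, neuron and voltage in the
error. Recording (1 ms stride for population mean current magnitudes) is
passive: doubling the stride changes no spike time, which is tested.
Random numbers come from derived seed streams (connectivity,
heterogeneity, inputs, fixtures) so that sweeps share one network
realization while varying input noise; replicate $r$ of a sweep uses input
seed $seed + r$.

## Measurement layer

**Capacity.** A group counts as maintained when at least 50% of its
excitatory neurons exceed 10 Hz in the last 200 ms of the delay. These
operational thresholds are package choices (the underlying definition —
"groups that keep discharging" — does not fix them); they are configurable,
recorded with every result, and capacity is tested to be monotone under
criterion relaxation and to agree with an independent brute-force rate
count on random fixtures.

**Intrinsic timescale.** Spike counts in 50 ms windows; per-unit lagged
Pearson correlations averaged across units (the default pooling, robust
for short spans; population-pooled correlation available by flag);
$\bar\rho(\Delta) = a(e^{-\Delta/\tau} + b)$ fit with Levenberg–Marquardt
(`minpack.lm::nlsLM`), initialized at $a = 1$, $b = 0$, $\tau = 2$ bins,
bounded $\tau > 0$. Zero-variance units are dropped (making the estimator
invariant to adding silent neurons); a fit with amplitude $|a| \le 0.05$
is flagged non-converged because $\tau$ is unidentifiable without a
decaying component — white-noise counts end up there. Epoch-anchored
estimates run the same pipeline from the start of the memory and cue
epochs, separately for E and I populations, pooling all groups by default
(restriction to chosen groups by argument).

## Synthetic fixtures

`makeCapacityRaster()` emulates exactly the two features the measurement
layer needs: a controllable set of groups firing Poisson spikes at a
sustained rate through the delay (default 40 Hz) while the rest fall
silent after the memory epoch. `makeAr1Counts()` produces
doubly-stochastic Poisson counts whose latent log-rate is AR(1) with
autocorrelation $e^{-\Delta/\tau}$ — the AR(1) lives on the log rate to
keep rates positive, and Poisson sampling attenuates the count
autocorrelation by a lag-independent factor only, so the latent $\tau$
remains recoverable. Defaults (30 units, 20 Hz mean rate, 0.5 log-rate
sd) were chosen once as a plausible cortical regime. What fixture-based
tests establish is that the estimators are correct on data matching their
assumptions; they do not establish that real rasters satisfy those
assumptions (stationarity within epochs, unit independence, exponential
decay), and simulation rasters violate them to varying degrees (e.g.
strong within-group correlations).

## Problem sizes

Desk-scale defaults throughout: 200 neurons, 2.9 s protocol span, 3×3
sweep grids with 3 replicates, 10 seeded repeats for the competition
demonstration, 20 seeds per timescale-recovery point. These are the sizes
the test suite and acceptance script run at; larger networks and grids are
configuration changes, not code changes.

## Known limitations

- The shared $(V-V_L)$ driving force means no distinct reversal potentials
  for excitation and inhibition; inhibition shunts toward rest rather than
  hyperpolarizing below it.
- Default parameters are stand-ins, not the unavailable published tables;
  quantitative outputs (absolute current magnitudes, exact capacity maps)
  are specific to the shipped configuration.
- No long-term plasticity, no spatial structure, no conductance-based
  channel dynamics, single global synaptic delay.
- $s_{NMDA}$ can exceed 1 transiently when $\gamma_{NMDA} > 1$ (see
  above).
- The homogeneous network is a deliberately crude control (uniform draws,
  no type distinctions), not a calibrated alternative model.
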