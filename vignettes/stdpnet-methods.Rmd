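---
title: "Feedforward structure from asynchronous stimulation: model and methods"
author: "stdpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedforward structure from asynchronous stimulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpnet)
```

## The model

`stdpnet` simulates a two-dimensional, layered network of excitatory leaky
integrate-and-fire neurons whose synapses evolve under spike-timing-dependent
plasticity (STDP), and asks how repeated *asynchronous* stimulation of
adjacent layer pairs sculpts the connectivity into a feedforward structure —
and how both the structural modification and the network's subsequent
signal-propagation ability decay with the inter-stimulus interval, with
decay constants that mirror the STDP time constants themselves.

### Geometry and connectivity

Neurons sit at the cell centres of an `nLayers x perLayer` lattice in the
unit square (default 50 layers of 20 neurons, N = 1000); layer 1 is the
leftmost column and global indices run left to right, so layer 3 holds
neurons 41–60.  Each unordered pair at Euclidean distance $d$ (in
side-length units) is connected with probability

$$p(d) = k\, e^{-d/\lambda_c}, \qquad k = 0.2,\ \lambda_c = 0.1,$$

clamped to $[0,1]$.  A connected pair receives **both** directed synapses
with independent initial weights drawn uniformly from $[0, 1]$ — the
reciprocal support is what lets the same training protocol potentiate one
direction while depressing its mirror.  The exponential kernel follows the
spatial-growth convention for locally connected networks; any
monotone-decreasing kernel can be substituted through
`connectivityConfig()`.

Synapses are classified relative to the training direction: *feedforward*
(presynaptic layer left of postsynaptic), *feedback* (right of), and
*recurrent* (same layer).  With $\lambda_c = 0.1$ (five inter-layer
spacings) roughly a quarter of the feedforward class connects strictly
adjacent layers; the rest spans two or more layers.  This has a consequence
discussed under *Limitations*.

### Membrane and synapse dynamics

Each neuron follows

$$\tau_m \frac{dV_i}{dt} = (V_{rest} - V_i)
  + g \sum_j a_{ji} W_{ji}\, s_j(t)\,(E_{ex} - V_i) + I_i(t),$$

with $\tau_m = 20$ ms, $V_{rest} = -70$ mV, threshold $V_{th} = -54$ mV,
excitatory reversal $E_{ex} = 0$ mV (standard V1-cell modelling values) and
currents in voltage-equivalent units.  On reaching threshold a neuron spikes
and resets to $V_{rest}$; there is no refractory period.  The synaptic
conductance $s_j$ is an alpha function, $(s/\tau_\alpha)e^{1-s/\tau_\alpha}$
with $\tau_\alpha = 2$ ms, realised as two coupled linear state variables
with *exact* per-step exponential updates so that overlapping spikes
superpose correctly; $g = 0.06$ scales the summed weighted conductance.

Integration is clock-driven with an exponential-Euler step
($\Delta t = 0.1$ ms default): conductance and current are frozen over the
step and the resulting linear ODE is advanced exactly.  For a constant
current with no synapses this reproduces the closed-form relaxation to
machine precision, which the test suite exploits as a micro-oracle; spike
times converge at first order in $\Delta t$.  Spikes are detected at step
end, and all spikes within one step are treated as simultaneous.  Alpha
states below $10^{-7}$ are dropped (membrane error below $10^{-6}$ mV),
which keeps long silent gaps cheap.

### Plasticity

Weight changes follow the nearest-spike pair rule: when neuron $i$ fires at
time $t$, every incoming synapse $j \to i$ whose presynaptic partner has
fired is potentiated by $A_+ e^{-(t - t_j)/\tau_+}$, and every outgoing
synapse $i \to j$ is depressed by $A_- e^{-(t - t_j)/\tau_-}$, using only
the partner's most recent spike.  Weights are clipped into $[0, 1]$ after
every update (hard bounds).  Defaults: $A_\pm = 0.1$, $\tau_\pm = 20$ ms
(the temporally symmetric form; unequal amplitudes or time constants give
the asymmetric form).

Synchronous spikes (same integration step) apply the potentiation amplitude
$A_+$ to **both** synapses of a reciprocal pair, once each.  This convention
is what drives the strong growth of recurrent weights: all neurons of a
stimulated layer are driven by the same pulse and fire near-synchronously.

### Training and testing protocols

One training trial for layer pair $(l, l+1)$: a pulse of amplitude $I_s$
into layer $l$ for $T_d = 5$ ms, a gap of $\Delta T$ ms (measured from pulse
*offset* to the next *onset* — at $\Delta T = 0$ the left spikes still
precede the right spikes by about $T_d$, which is what makes the zero-gap
condition maximally feedforward rather than symmetric), the same pulse into
layer $l+1$, and a settling window of at least $10\tau_\alpha$.  All
membrane and synaptic state, including the spike-time memory, is then reset
to rest — the exact-reset equivalent of a long recovery period — while
weights persist.  One sweep trains every adjacent pair left to right;
20 sweeps is the reference dose.

$I_s$ is calibrated once per configuration: the smallest amplitude on a
1 mV grid that makes *every* neuron of a stimulated layer fire within
$T_d$, verified to recruit no spikes outside the stimulated layer
(`calibrateStimulus()`; the grid starts at the closed-form single-neuron
threshold $(V_{th}-V_{rest})/(1 - e^{-T_d/\tau_m})$, about 72.3 mV at the
defaults).

Propagation is probed with a steady current $I_t$ into layer 3 for 200 ms
with plasticity frozen; the propagation count $S$ totals the spikes of all
layers right of the target.  The default $I_t$ is **three** times the
calibrated $I_s$: it is the smallest integer multiple at which the fully
trained reference network propagates at all — at twice the calibrated
amplitude the trained and untrained counts coincide and the dynamics carry
no signal.  The relation analyses (below) use a stronger drive; see
*Measuring the falloff constants*.

## Measuring the falloff constants

### Structure: the interior-shift estimator

Because the dynamics are deterministic and trials repeat identically, the
protocol shifts every *paired* synapse of a class by the same cumulative
amount $c(\Delta T) = n_{trials} A_\pm e^{-\mathrm{lag}/\tau_\pm}$.  The raw
class-mean modification $\Delta G$ (mean weight minus its initial 0.5) is
flattened whenever $c$ drives weights into the hard bounds — at the default
amplitude ($A = 0.1$, 20 trials) the cumulative shift at short intervals
exceeds the whole weight range, so a log-linear fit of $\Delta G(\Delta T)$
is biased upward by tens of percent.

`pairingShift()` therefore estimates $c$ from the synapses that end
*strictly inside* the bounds: each such synapse carries the shift exactly,
and the median over interior synapses recovers it regardless of how many
neighbours were clipped.  Intervals with no interior survivor are reported
censored and excluded from the fit.  `structuralFalloff()` fits
$c(\Delta T)$ log-linearly; on the reduced lattice (below) it recovers the
programmed $\tau_\pm$ to well within a percent in expectation, and the
potentiation constant is invariant under the depression branch's parameters
(and vice versa), because the two branches update disjoint synapse sets.

### Dynamics: floor-corrected spike-count falloff

$S(\Delta T)$ does not decay to zero: recurrent potentiation is independent
of the interval and lifts the count uniformly.  `sweepInterval()` therefore
also trains a *reference* network at an interval far beyond the STDP window
(200 ms default) — structurally identical except that the feedforward /
feedback modification has vanished — and `dynamicalFalloff()` fits the
excess $S - S_{ref}$ log-linearly.  When no reference is available the
floor is instead fitted as a free offset by bounded nonlinear least squares
(`fitExponential(..., offset = TRUE)`).

Spike counts fluctuate between network realisations (the propagation
pattern is sensitive to the realized connectivity), with a between-seed
standard deviation of a few spikes; intervals whose mean excess is below
twice that noise scale carry no decay information and are excluded.

Two regime choices matter here, both made from the censoring arithmetic and
a linearity measurement rather than from any fit outcome:

* **Pairing amplitude.** The relation experiments run at $A = 0.025$, so
  that $20 \cdot A \cdot e^{-\mathrm{lag}/\tau}$ stays below half the weight
  range for every $\tau$ in the sweep — the hard bounds then censor nothing
  and $\Delta G$ itself is exponential in $\Delta T$.  Spike counts, unlike
  weights, cannot be un-censored after the fact, so the experiment must be
  run in the linear regime rather than corrected later.
* **Test amplitude.** At weak drive the propagation count responds as a
  thresholded (convex) function of the structural modification — a
  downstream neuron needs enough summed conductance before any extra weight
  produces extra spikes — which distorts the fitted decay constant,
  compressing it for fast kernels and inflating it for slow ones.  The
  population response linearises as the drive recruits more of each layer
  (visible directly in the structure–dynamics coefficient $\kappa(I_t)$,
  which grows steeply with drive), so `relationReport()` measures the
  dynamical falloff at nine times the calibrated training amplitude, over
  an interval grid densified at small $\Delta T$ and a 500 ms counting
  window so that fast kernels still contribute several points above the
  count-fluctuation floor.

`relationReport()` assembles the full picture: structural and dynamical
falloff constants per STDP setting, the linear fit of $\tau_{dyn}$ against
$\tau_+$ (slope close to 1), and $\kappa(I_t)$ from the regression of the
excess count on $\Delta G^+$.

## Problem sizes and runtimes

The reference lattice is 50 x 20 (N = 1000); a full 20-trial training takes
a few seconds in the compiled core.  Weight-distribution and conservation
measures are computed at full size.  The structural falloff sweeps use a
reduced 20 x 10 lattice (N = 200, same kernel in side units), where the
interior-shift estimator is still exact in expectation; three seeds suffice
because the per-synapse shifts are deterministic.  The dynamical relation
sweeps run at full size — the reduced lattice is too sparse to propagate —
with two seeds and the densified interval grid.  These sizes are the
package's default experiment design, reproduced by `scripts/acceptance.R`.

## What the defaults do and do not reproduce

With the exponential kernel at $k = 0.2$, $\lambda_c = 0.1$, the trained
network reproduces the qualitative programme in full: feedforward weights
pile up at the upper bound and feedback weights at the lower bound, with the
saturated share falling steeply with the interval; the structural
modification of both branches decays exponentially with constants equal to
$\tau_+$ and $\tau_-$; symmetric STDP conserves modification (potentiation
gain equals depression loss to within ~2%) while asymmetric STDP breaks the
balance in the direction of the stronger branch; propagation is
overwhelmingly rightward and its falloff constant tracks $\tau_+$ with unit
slope.

Three quantitative claims are *not* reproduced at these defaults, all for
one structural reason: multi-layer-span synapses.  Only adjacent-layer
synapses ever experience a pre/post pairing under adjacent-pair training,
and with $\lambda_c$ spanning five layers they are only ~25% of the
feedforward class.  Hence (i) the saturated share at $\Delta T = 0$ tops
out near 16% rather than ~62% — matching the larger printed share would
require the connection footprint to be about one layer spacing, which at
$k = 0.2$ would leave the network too sparse to propagate at all; (ii) a
handful of spikes leak into the layers left of the test target through
*untrained* two-span feedback synapses sitting at their initial weights;
and (iii) removing feedback and recurrent connections shifts the
propagation count by about 10% rather than being fully negligible.  The
package reports these measures as computed; the acceptance suite asserts
the printed values and is allowed to stay red there.

Two further caveats.  Recurrent modification is only *approximately*
independent of the interval (coefficient of variation ~7% across a sweep,
against an asserted 5%): at small gaps, leftover alpha-kernel drive from
the left layer desynchronises the right layer's firing by a step or two,
so some reciprocal recurrent pairs receive one potentiation and one
depression instead of two potentiations.  And all synthetic conditions
share the model's idealisations — purely excitatory coupling, no conduction
delays, no background noise, exact state resets between trials — so green
tests certify the implementation against its own model, not the behaviour
of biological tissue.

## Numerical choices

* Exponential-Euler membrane updates: exact for frozen conductance, stable
  at any step; spike times converge at first order.
* All spikes within one step are synchronous for plasticity
  ($\Delta t_{pair} = 0$); reciprocal pairs then receive a single $+A_+$
  each, applied once (the incoming pass owns the synchrony update).
* Weight clipping after *every* pairwise update, not per step.
* Fits: log-linear least squares on $(x, \log y)$, exact on noiseless
  exponentials; non-positive points are dropped with a warning, fewer than
  three survivors is an error, and a non-negative slope yields an object
  flagged invalid.  The offset variant uses `stats::nls` (port algorithm)
  with starts from the data range.
* Saturation tolerance for "at the bound" is 0.01 weight units.
* Networks serialise to Matrix Market coordinate files in which
  depressed-to-zero synapses remain explicit entries, so adjacency support
  survives the round trip.

## A small worked example

```{r example, eval = FALSE}
cfg <- defaultConfig("scaled", seed = 1)
net <- generateNetwork(cfg@geometry, cfg@connectivity, seed = 1)
iS  <- calibrateStimulus(net)

trained <- trainNetwork(net, trainingProtocol(iS = iS, deltaT = 0,
                                              nTrials = 20))$network
summarizeWeights(trained)$table

tab <- sweepInterval(cfg, deltaT = seq(0, 60, 10), nSeeds = 3,
                     refInterval = NULL)
structuralFalloff(tab, "potentiation")
```
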