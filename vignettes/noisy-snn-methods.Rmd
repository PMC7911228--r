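---
title: "Methods: noisy LIF networks, latency coding, supervised STDP and synapse growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noisy LIF networks, latency coding, supervised STDP and synapse growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnlab)
```

`snnlab` simulates small spiking neural networks in which a constant or
Gaussian background current — a stand-in for diffuse resting-state brain
activity — is injected into leaky integrate-and-fire (LIF) neurons while the
network classifies latency-coded digit images or grows lateral synapses.
This vignette records the model, the numerical choices, and the design
decisions that were genuinely open, in enough detail to audit or re-derive
every quantity the package computes.

## The neuron model and its integrator

Each neuron follows the LIF membrane equation
$$\tau_m \frac{du}{dt} = -(u - E_L) + R\, I(t),$$
with threshold/reset: when $u$ crosses $V_{th}$ a spike is emitted, $u$ is
reset to $V_{reset}$ and clamped there for the refractory time $t_{ref}$.
Defaults are the NEST iaf values: $\tau_m = 10$ ms, $C_m = 250$ pF
($R = \tau_m / C_m = 40\,\mathrm{M\Omega}$), $E_L = V_{reset} = -70$ mV,
$V_{th} = -55$ mV, $t_{ref} = 2$ ms, $dt = 0.1$ ms.

Integration uses the **exact exponential update** for piecewise-constant
input, $u' = u_\infty + (u - u_\infty)e^{-dt/\tau_m}$ with
$u_\infty = E_L + R I$, not forward Euler. The rheobase
$I_{rh} = C_m (V_{th} - E_L)/\tau_m = 375$ pA is then exactly the boundary
current at any step size: at 375 pA the fixed point *equals* threshold and
the trajectory approaches it strictly from below, so the neuron never fires,
while 376 pA fires at $\tau_m \ln\!\big((u_\infty - E_L)/(u_\infty -
V_{th})\big) \approx 59$ ms. Euler integration would smear this boundary
with $dt$.

Two deliberate numerical choices:

* **Threshold crossing is strict** ($u' > V_{th}$). At exactly rheobase the
  gap $V_{th} - u$ shrinks below double-precision resolution after roughly
  376 ms and $u$ rounds to exactly $V_{th}$; a non-strict test would then
  fire a neuron that mathematically never crosses. Strictness realizes the
  intended approach-from-below semantics in floating point. A trajectory
  that genuinely crosses threshold passes through equality only on a
  measure-zero set of parameters, so nothing else changes.
* **Spikes are recorded at the end of the step** in which the crossing
  happens; there is no within-step interpolation. All boundary quantities
  reported by the package are robust to this $\le dt$ latency.

## The noise generator

The background drive is a per-tick Gaussian current
$I_k = \mu + \sigma \eta_k$, $\eta_k \sim \mathcal N(0,1)$ i.i.d., drawn
once per refresh interval (default: the simulation step) and held constant
within it. This copies the NEST noise-generator semantics — draws are **not**
scaled by $1/\sqrt{dt}$, so the variance of the integrated membrane
fluctuation depends on the refresh interval. This is stated loudly because
it deviates from a true white-noise (Wiener) discretization; it is the
semantics under which the package's headline parameter values (e.g.
$\mu = 400$ pA, $\sigma = 0$) are meaningful. Each attached neuron owns an independent seed
stream derived from the generator seed and the neuron index, mirroring
one-to-one generator wiring. With $\sigma = 0$ the noisy simulation reduces
*exactly* to the deterministic one.

## Latency encoding and preprocessing

A pixel value $V \in [0, 255]$, normalized to $v = V/255$, is encoded as one
spike at
$$S = (v - 1)^2\,(T_{stop} - T_{start}) + T_{start},$$
a strictly decreasing bijection of brightness onto the window
(default $[0, 10]$ ms; presentations are separated by a 5 ms silent gap).
Brighter pixels fire earlier and the law is steepest near bright values, so
early spikes carry the most information (rank-order coding). The
normalization of $V$ to $[0,1]$ is required for the quadratic law to stay
inside the window; the raw 0–255 range would explode the square.

The three-layer network preprocesses the 28×28 image with four fixed 4×4
kernels (uniform average, horizontal-, vertical- and diagonal-edge), valid
stride-1 convolution (25×25), then 2×2 stride-2 pooling with floor
truncation (12×12; max pooling by default, mean available). The kernels are
deterministic and parameter-free by design: a fixed, unlearned convolution
front end conventionally extracts smoothed-intensity and edge features, and
fixing them keeps every experiment free of hidden trainable state.
Each channel is rescaled onto $[0, 255]$ so it can be latency-encoded like a
raw image.

## Networks and synaptic events

* **Two-layer**: 784 relay input neurons (one per pixel), each with its own
  noise generator, fully connected to 10 output LIF neurons
  (784 × 10 = 7840 plastic synapses). Input neurons are *relays*: the
  encoded pixel time forces a spike regardless of membrane state, which
  makes the encoding law exact at layer 1 without committing to a drive
  amplitude for the encoded event.
* **Three-layer**: the four 12×12 channels map one-to-one onto 576 memory
  LIF neurons; a seeded random subset (default round(0.2·576) = 115,
  configurable to exactly 120) receives noise generators; memory projects
  fully onto 10 outputs; lateral memory synapses start empty (optionally
  from a sparse random prior) and grow structurally.

Each presynaptic spike delivers a **delta-current pulse** of amplitude
$w \cdot I_{syn}$ (default $I_{syn} = 600$ pA at $w = 1$) lasting one step:
a membrane jump of $w R I_{syn}(1 - e^{-dt/\tau_m}) \approx 0.24 w$ mV. The
output layer is integrated **event-driven** — exact exponential decay
between jump times — which is algebraically identical to the grid update
but steps only at input events. Decoding: earliest output spike, ties
broken by larger spike count, then lowest index; if no output spikes the
label falls back to 0 with a no-spike flag.

## Supervised pair-based STDP

The plasticity kernel is the pair-based window
$$f(\Delta t) = \begin{cases} A_+ e^{-\Delta t/\tau_+} & \Delta t > 0\\
 -A_- e^{\Delta t/\tau_-} & \Delta t < 0 \end{cases}$$
with $f(0) := 0$ (the branch limits disagree and simultaneous spikes carry
no causal order), accumulated over **all pairs** within one presentation
window (presentations are independent trials; no cross-image pairing).
Defaults are the canonical pair-based values $A_+ = 0.005$,
$A_- = 1.05 A_+$, $\tau_\pm = 20$ ms; weights are hard-clipped to $[0, 1]$
and initialized i.i.d. uniform on $[0.3, 0.7]$ under the experiment seed.
$\tau_\pm$ is configurable down to $\tau_m = 10$ ms for readers who take
the membrane constant literally as the STDP constant.

The supervisory rule: synapses onto the **true-label** output receive the
all-pairs sum times `rewardMatched` (+1); synapses onto any **other output
that spiked** receive `rewardMismatched` times the *magnitude* of their
pair sum (keeping the update timing-sensitive rather than a flat penalty).

One default required calibration. With 10 outputs and a decode rule under
which, at cold start, essentially every output spikes in every
presentation, a symmetric mismatch reward of $-1$ depresses nine outputs
for every one potentiated: all weights decay to zero, and silence is
absorbing because matched potentiation itself needs post spikes. The
mismatch magnitude must therefore scale like $1/(n_{out}-1)$; the default
is $-0.15$, slightly above the balance point $1/9$, which leaves a gentle
net decay of uninformative weights while class-specific afferents grow.
With this default the synthetic-digit task (200 train / 100 test, 5
iterations) reaches roughly 0.4–0.5 held-out accuracy versus 0.1 chance.
On a two-class toy problem the natural balance is $-1$ again, which the
tests use.

## The noise-mean sweep and what it can show

`sweepNoiseMean()` trains the two-layer network per noise mean
$\mu \in \{2, 4, \ldots, 30\}$ pA plus the $\mu = 0$ baseline, at matched
seeds (identical dataset and initial weights across the grid), and reports both
held-out accuracy and the improvement
$\Delta(\mu) = \mathrm{acc}(\mu) - \mathrm{acc}(0)$, so either view of the
noise benefit can be read off directly. One property is worth stating
plainly: with $\sigma = 0$ (the default sweep keeps the standard deviation
at zero) and relay inputs, a subthreshold constant bias can neither
move a forced spike time nor create a spike, so the sweep is **provably
flat** — $\Delta \equiv 0$ at every grid point. The package reports what the
model produces rather than engineering a peak; the sweep machinery becomes
informative for $\sigma > 0$ or suprathreshold means, both supported.

## Structural growth

The growth rule is a minimal Hebbian coincidence detector — the most
parsimonious mechanization of "B's trigger follows A's, persistently";
every ingredient is package-defined and configurable: for every ordered pair of
distinct neurons within Chebyshev radius 3 on the memory grid — the four
12×12 channels tiled 2×2 into a 24×24 map — causal spike pairs with
$0 < t_j - t_i \le 10$ ms are counted, the counts **accumulate across
presentations**, and a synapse $i \to j$ (initial weight 0.5) is created
when the cumulative count reaches 2. Synapses are never removed.
Accumulation across presentations is essential: under stimulus-only drive
each neuron spikes once per presentation, so a within-presentation
threshold of 2 could never be met and the stimulus condition would grow
nothing.

The three conditions — (a) stimulus only, (b) noise only, (c) both — run at
matched seeds with $\mu = 400$ pA, $\sigma = 0$ (suprathreshold: rheobase
is 375 pA), 20 presentations per run, over a 20-image stimulus set. Two
further choices make the comparison meaningful:

* **Initial membrane potentials** are drawn uniform on
  $[V_{reset}, V_{th})$ per neuron under the run seed. With $\sigma = 0$
  every noisy neuron receives an *identical* constant current; starting
  them all at rest would synchronize their spikes exactly and the strictly
  causal rule would count nothing in condition (b). Random initial phases
  are also the physically sensible state of a network that was not just
  reset.
* **Non-informative pixels are tailored out of the memory drive**: only
  pixels with a strictly positive raw filter response force a spike —
  the thresholding view of neuronal preprocessing, under which white
  background pixels carry no information worth transmitting. It also
  matters dynamically —
  if every neuron were reset by a forced spike every 15 ms presentation,
  the 27.7 ms noise-driven climb to threshold could never complete and
  condition (c) would collapse onto (a) exactly.

At these settings condition (b) grows a few hundred synapses among the
noisy neurons, (a) grows ~10–11 thousand along stimulus structure, and (c)
exceeds (a) by roughly 10–15% at every seed; the package asserts only the
ordering (c) > (a) and (b) > 0, since the absolute counts are properties of
the artifact-defined rule.

## The synthetic digit generator

Tests and experiments run on a procedural generator, not on downloaded
data: seven-segment stroke templates for the digits 0–9 drawn at width 3 on
the 28×28 canvas, graded at the edges by a 3×3 binomial blur, with seeded
integer translation jitter (default ±1 px) and salt noise (default 2% of
pixels set to 255), labels assigned round-robin. The generator emulates the
aspects of handwritten digits the model actually consumes — bright strokes
on dark background, class-specific stroke geometry, small positional
variability — and nothing else: there is no stroke-width or slant
variation, no grey-level texture, and classes are far more separable than
handwritten digits. Passing tests therefore validate the simulation and
learning machinery, not handwriting-recognition performance; an IDX
reader/writer is provided so real MNIST files can be swapped in unchanged.

## Problem sizes and reproducibility

The shipped experiment defaults are desk-scale choices: 200/100 train/test
images, 5 training iterations, 5 seeds for the accuracy sweep; 20
presentations and 10 seeds for the growth comparison; 151-point integer
current sweeps for the firing boundary. Every experiment returns a manifest
(full parameter set and seeds) from which `rerunExperiment()` replays the
run — bitwise for deterministic runs, identically given seeds for
stochastic ones.

## Known limitations

* The mismatch-reward calibration above is specific to the earliest-spike
  decode with all-pixels encoding; other decoders would need their own
  balance.
* The noise-benefit question cannot be answered affirmatively at
  $\sigma = 0$ with relay inputs (see above); the package states this
  rather than simulating around it.
* The growth rule, the convolution kernels, and the synaptic pulse shape
  are package-defined conventions; all are exposed as configuration so
  alternative choices can be tested.
* Conductance-based synapses, adaptive/exponential LIF variants, triplet or
  nearest-neighbour STDP, synaptic pruning, and multiplicative or 1/f noise
  are out of scope.
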