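---
title: "Unsupervised spiking networks with pruning during training: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised spiking networks with pruning during training: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeprune)
```

## The model

`spikeprune` simulates a single-layer, fully connected spiking neural network
that learns to classify grayscale images without supervision, together with an
activity-triggered scheme for pruning synapses *while the network is still
training*. The network is defined by `n` input neurons (one per retained pixel,
plus one always-on bias input), `m` output neurons, and an `m x n` weight
matrix `W` with entries confined to `[-1, 1]`.

**Rate coding.** Each pixel intensity `x` in `[0, 1]` is encoded as a Poisson
spike train at rate `x * 200` Hz, with event times rounded to the 1-ms
simulation grid. We realize this as independent Bernoulli trials per
millisecond bin with success probability `x * 0.2`; at 200 Hz and 1-ms bins
this is statistically indistinguishable from thinning a continuous Poisson
process and rounding, and it collapses same-millisecond events exactly the way
rounding does. During training each sample is presented for 50 ms but
displayed only for the first 40 ms; the 10-ms silent tail prevents the
previous sample's input spikes from being potentiated against the next
sample's output spikes.

**Winner-take-all firing.** Output firing is gated by a single global 200-Hz
Poisson process: in each millisecond, with probability 0.2, exactly one output
neuron fires. The firing neuron is drawn from the softmax of the instantaneous
membrane potentials `u_k = sum_i W_ki x_i(t)`, where `x(t)` is the binary
input-spike snapshot of that millisecond. Potentials are inner products
evaluated only at firing steps — there is no integration, leak, threshold,
reset, refractory period, or lateral inhibition. A single global gating
process (rather than per-neuron processes) is what makes "10 expected output
spikes per 50-ms presentation" hold for the layer as a whole.

**Plasticity.** When output neuron `k` fires at `t_out`, every one of its
unpruned synapses is classified: LTP if its input's most recent spike
satisfies `0 <= t_out - t_in < 10` ms, LTD otherwise (including inputs that
have never spiked). The window is strict at 10 ms: an input spike from the
last displayed millisecond of the previous sample, seen from the first
millisecond of the next presentation, is exactly 10 ms old and must *not* be
potentiated — that is the entire purpose of the silent tail. Magnitudes are

* LTP: `dw = a * exp(-b (w + 1))`, with `a = 0.0667`, `b = 2.5` — equal to
  `a` at the lower bound and decaying toward zero as `w` approaches 1, which
  makes potentiated weights converge to the upper bound;
* LTD: `dw = -c`, with `c = 0.0167`, constant in `w`; depressed weights are
  clipped at the lower bound.

Each event's LTP steps are scaled by `d/n` and its LTD steps by `p/n`, where
`p` and `d` are the event's LTP/LTD counts. Since every unpruned synapse is
touched each event (`p + d = n`), the two branches move equal total mass in
opposite directions, keeping the weight distributions of all output neurons
on a common scale without explicit mean/variance normalization. With a
constant LTP form of magnitude `c` the cancellation is exact, which the test
suite asserts to 1e-12.

**Labeling and testing.** After training the weights are frozen. One pass
over the training set (same 200 Hz / 50 ms machinery) accumulates spike
counts `N_kj` per neuron and class; response probabilities are
`Z_kj = N_kj / sum_j N_kj`, each neuron is labeled `argmax_j Z_kj`, and
neurons whose maximum response probability falls below the removal threshold
(0.75), or that never spiked, are excluded. A test sample is presented for
200 ms under a 600-Hz output gate and predicted as the class whose labeled
population has the highest mean spike count, ties toward the lower class
index.

**Pruning during training.** A neuron that produces a run of at least 8
consecutive output spikes within one sample's 40-ms display window earns one
consistent-firing count; at `r = 10` counts a user-set percentage of its
weights is pruned, once per neuron per run. A maximal run counts once
regardless of length (at ~8 expected events per window, two disjoint runs of
8 in one presentation are effectively impossible anyway), and runs never span
presentation boundaries. Two selection rules are provided:

* conventional pruning: the weights of smallest magnitude are set to 0;
* soft-pruning: the lowest-valued weights are frozen at the lower bound -1 —
  the natural choice for images whose background is a single saturated
  "off" level while the foreground carries graded intensity.

Frozen synapses are excluded from classification and from the scaling
denominator `n`, so the LTP/LTD balance stays exact among the synapses that
still move (the alternative convention — `n` fixed at the total synapse
count — is available via `stdp_config(scale_n = "total")`). Pruning the
whole network once after training (`prune_after_training`) is included as
the baseline this scheme is compared against.

**Crossbar export.** For memristive in-memory implementations, trained
weights map linearly onto a device conductance range:
`G = W (G_max - G_min)/2 + (G_max + G_min)/2` for a single device per
synapse, or a two-device differential pair with `G = G+ - G-`, split as
`G+ = G_min + max(W, 0) dG`, `G- = G_min - min(W, 0) dG` so that both
devices stay in range and at most one leaves its floor per synapse. Device
bounds are user configuration; no device nonlinearity or variability is
modeled.

## The synthetic fixture

The package ships no external data; `generate_synthetic()` builds a
class-prototype image set that reproduces the features the network actually
exploits in handwritten digits: a sparse graded foreground on an exactly-zero
background. Class `c` occupies a fixed horizontal band of rows (disjoint
supports across classes); each sample multiplies the band by i.i.d. uniform
intensities from `[0.5, 1]`, and isolated salt noise flips background pixels
with probability 0.02 — low enough that every true background pixel stays
zero in well over 95% of samples, so the background filter is exercised end
to end and removes exactly the inter-band rows and margins.

Defaults (4 classes, 200 samples per class, 28 x 28 grid) were fixed once, on
fidelity grounds: the grid matches real digit images, so a sample's
foreground (~150 pixels) drives the network at the same absolute input-spike
rates as the real data. That absolute scale matters: the softmax sharpness —
and with it both the emergence of selective neurons and the consecutive-spike
runs that trigger pruning — grows with the number of coincident input spikes
per millisecond, so a miniature grid would put the simulation in a
qualitatively different (diffuse-firing) operating regime in which
activity-triggered pruning never engages.

What the fixture does *not* emulate: within-class shape variability (every
sample of a class shares one support), overlapping class supports, stroke
thickness and deformation, or anti-aliased edges. Tests passing on this
fixture therefore demonstrate that the learning rule, labeling, pruning
triggers, and the pruning/accuracy trade-off behave as designed — not that
any particular accuracy carries over to real handwriting.

## Numerical and design choices

* **Weight updates are clipped to `[-1, 1]` after every event**, not only for
  LTD: the exponential LTP respects the bound only asymptotically, and a
  scaled floating-point step can overshoot by rounding.
* **Last-input-spike times live on a global clock** and persist across
  presentation boundaries; classification of a spike as "too old" then falls
  out of plain subtraction, including across samples.
* **Input spikes at the event's own millisecond count as coincident**
  (`dt = 0` is LTP): the snapshot that produced the potential is the
  strongest evidence of correlation.
* **Prune selection size** is `round(percentage * n)` with half away from
  zero; ties in magnitude or value break toward the lower synapse index.
  Both choices are arbitrary but deterministic.
* **Removal threshold semantics**: the labeling-phase threshold (0.75) is
  applied to each neuron's maximum class-response probability; response
  probability is the only labeling statistic, so it is the natural quantity
  to threshold. Neurons with no spikes at all are always removed.
* **Test presentations display the input for the full 200 ms.** The silent
  tail exists to protect plasticity from cross-sample coincidences; with
  weights frozen it serves no purpose. This is a choice, not a constraint of
  the model — `encoding_config()` exposes the window explicitly.
* **Seeding**: a master seed fans out to independent phase seeds (data,
  weight init, training, labeling, testing) via `derive_seed()`. Within a
  presentation, draws occur in a fixed order (event gate for all steps, then
  one draw per event), so runs differing only in pruning mode consume the
  stream identically and stay event-identical until the first prune changes
  the weights — the construction used to compare pruning modes on equal
  footing.

## Problem sizes

The shipped study conditions — 4 classes x 200 samples, 100 output neurons,
2 training epochs, 50 test samples per class — run the full pipeline
(train, label, test, twice for the pruning comparison) in a few minutes on
one CPU while reproducing the qualitative results: test accuracy well above
3x chance, a 50% soft-pruned run within a few points of the unpruned run,
roughly 6-9% fewer synapse updates with 6-8 of 100 neurons pruning during
the two epochs (the update saving grows with epochs, since pruned neurons
stop paying for half their synapses from the prune point on), and identical
event streams up to the first prune. Larger networks, more epochs, or IDX
datasets (e.g. the real digit images) are a matter of configuration, not
code: `read_idx()` accepts the standard big-endian uint8 container.

## Known limitations

* Pure-R event loop: adequate for the shipped problem sizes (tens of
  thousands of presentations); a 60,000-image, 500-neuron, 3-epoch run is
  hours, not minutes.
* Single layer only; no population input coding, no convolution.
* The conductance map is ideal and noiseless; circuit-level energy, latency
  and area are out of scope.
* Soft-pruning freezes weights at the lower bound only; freeze-at-current
  value and consolidation variants are not implemented.
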