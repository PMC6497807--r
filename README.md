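# spikeprune

Unsupervised learning with a single-layer spiking neural network, and
synaptic pruning applied *during* training.

`spikeprune` is for researchers studying energy-efficient online learning on
neuromorphic substrates (memristive / eNVM crossbar arrays), where every
synaptic weight update costs a device write. It implements:

* **Poisson rate coding** — pixel intensity `x ∈ [0,1]` becomes a spike
  train at `x · 200` Hz on a 1-ms grid, displayed for the first 40 ms of
  each 50-ms training presentation;
* **Softmax winner-take-all firing** — a single global 200-Hz Poisson
  process gates output events; the firing neuron `k` is drawn with
  probability `exp(u_k) / Σ_i exp(u_i)` from the instantaneous membrane
  potentials `u_k = Σ_i W_ki X_i + b_k` (no integration, threshold, leak or
  refractory period);
* **Simplified STDP** — at each output event every synapse of the winner is
  potentiated if its input spiked within the strict 10-ms window
  (`Δw = a·e^{−b(w+1)}`, a = 0.0667, b = 2.5) and depressed otherwise
  (`Δw = −c`, c = 0.0167), with LTP scaled by `d/n` and LTD by `p/n`
  (`p`, `d` = LTP/LTD counts, `p + d = n`) so the two branches stay in
  balance, and weights confined to `[−1, 1]`;
* **Pruning during training** — a neuron that fires ≥ 8 consecutive spikes
  within a sample's display window earns a consistent-firing count; at
  `r = 10` counts a user-set percentage of its weights is pruned, once per
  neuron. Conventional pruning zeroes the smallest-magnitude weights;
  *soft-pruning* freezes the lowest-valued weights at −1 — trading no
  storage saving for far more prunable weights and an almost unchanged
  weight distribution. Prune-after-training baselines are included;
* **Labeling and testing** — neurons are labeled by class-response
  probability `Z_kj = N_kj / Σ_j N_kj` over a labeling pass (neurons with
  max `Z < 0.75` are removed), and test samples (200 ms, 600-Hz output
  gate) are predicted by the labeled population with the highest mean spike
  count;
* **Crossbar export** — trained weights map linearly to device conductances,
  `G = W(G_max − G_min)/2 + (G_max + G_min)/2`, or to differential pairs
  `G = G⁺ − G⁻`;
* **Data input** — IDX image/label files (the MNIST container), plus a
  deterministic synthetic generator of sparse-foreground class-prototype
  images so the whole pipeline runs without downloads.

## Worked example

Train on the synthetic 4-class fixture, once without pruning and once with
50% soft-pruning during training, sharing one master seed:

```r
library(spikeprune)

cfg <- default_run_config(seed = 1)        # 4 classes, 28x28, 100 neurons, 2 epochs
off <- run_experiment(cfg)

cfg$prune$mode <- "soft"
cfg$prune$percentage <- 0.5
soft <- run_experiment(cfg)

off$result$accuracy          # 1.0   -- unpruned test accuracy (200 samples)
soft$result$accuracy         # 1.0   -- 50% soft-pruned, same seed
off$fit$state$update_count   # 9954375 synapse updates
soft$fit$state$update_count  # 9073906 -- ~8.8% fewer, 8 neurons pruned mid-run
print(soft$fit$state)
#> snn_network: 100 output x 625 input neurons
#>   weights in [ -1.000 , 0.977 ] | pruned neurons: 8 | frozen synapses: 2504
#>   clock: 80000 ms | synapse updates: 9,073,906
```

Both runs classify the held-out samples perfectly; the soft-pruned network
did so while skipping ~880,000 weight updates — the saving the method exists
for. (The fraction grows with training length: each pruned neuron stops
updating half its synapses from its prune point onward.)

A YAML config plus the thin CLI wrapper drives the same pipeline from a
shell:

```sh
Rscript inst/cli/snn.R train --config my_run.yaml --out out/
Rscript inst/cli/snn.R evaluate --checkpoint out/checkpoint.rds --out out/
Rscript inst/cli/snn.R sweep --config my_run.yaml --axis prune_pct --values 0,0.25,0.5,0.75
```

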