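# hhnet

Synapse models and network topology jointly decide how well a spiking
neuronal network synchronizes and how much input interference survives
transmission.  `hhnet` studies this with biophysical building blocks: 100
Hodgkin-Huxley neurons, one of which is driven by a sine current (optionally
corrupted by Gaussian white noise), coupled into a ring or a hub-augmented
Newman-Watts small-world graph by one of three synapse models —

* **ES**, electrical (gap junction): `I = g (V_pre − V_post)`, bidirectional;
* **HS**, Hansel-type chemical: `I = g H(V_pre(t−τ) − V_thresh)`, a
  constant-amplitude threshold-gated current, unidirectional and delayed;
* **RS**, Rabinovich-type chemical:
  `I = g (V_rev − V_post) H(V_pre(t−τ) − V_thresh)`, the same gate with
  postsynaptic feedback toward a reversal potential.

Each neuron follows the HH membrane equation
`C dV/dt = g_Na m³h (E_Na−V) + g_K n⁴ (E_K−V) + g_L (E_L−V) + I(t)` with the
canonical rate functions; the network is integrated as a delay-coupled
system with fixed-step RK4 (compiled core, dt = 0.01 ms).  Synchrony is
quantified by the Pearson correlation r of membrane-potential traces for
the reference neuron pairs (1,25), (15,30), (20,35), (5,45), and
propagation by first-spike latency relative to the stimulated neuron.
The methods vignette (`vignettes/hh-network-synchrony.Rmd`) documents every
model, default and numerical choice.

Intended users: computational neuroscientists and students comparing
coupling mechanisms or topologies under noise, and anyone needing a small,
fast, fully reproducible delay-coupled HH network simulator with an
explicit experiment grid.

## Worked example

A directed ring of 100 RS-coupled neurons, neuron 1 driven by
`I(t) = 60 sin(0.1πt) + 30` μA/cm² for 300 ms:

```r
library(hhnet)

ring <- build_ring(100, directed = TRUE)
res  <- simulate_network(ring, synapse_spec("RS"), stimulus_spec("sine"))
res
#> <hh_sim> 100 neurons, 300 ms (RS coupling, sine stimulus)
#>   neurons spiking: 100/100; total spikes: 835
#>   config 102a928d

correlation_table(res)
#>      pair  i  j           r defined
#> 1  r_1_25  1 25  0.08672217    TRUE
#> 2 r_15_30 15 30 -0.07207673    TRUE
#> 3 r_20_35 20 35 -0.08326521    TRUE
#> 4  r_5_45  5 45 -0.01916728    TRUE

first_spike_latency(res)[c(1, 2, 25, 100), ]
#>  neuron first_spike_ms latency_ms
#>       1      0.9172786   0.000000
#>       2      4.0620978   3.144819
#>      25     72.8422247  71.924946
#>     100    297.0922246 296.174946
```

Reading the output: every neuron fires (the RS current at rest, 6.5 μA/cm²,
is just suprathreshold), but each hop costs the 1 ms synaptic delay plus a
spike-initiation time, so activity crawls around the ring — neuron 25 fires
72 ms after neuron 1 and neuron 100 only near the end of the window — and
the fixed per-hop offset keeps raw-trace correlations small.  Replacing the
ring with the small-world hub graph (`build_nw_hub(100)`) collapses the
distal latency to ~12 ms and raises the correlation of co-driven pairs such
as (5,45) to ~0.79: shortcuts, not stronger synapses, are what buy
synchrony here.

The whole comparison grid (3 synapses × {ring, NW} × {sine, sine+noise},
noise conditions averaged over 10 seeds) is one call:

```r
grid <- run_experiment_grid(experiment_config())   # ~1 min
summarize_grid(grid)$correlation$RS
```

or from a shell, writing the per-synapse tables and latency CSVs:

```sh
Rscript inst/cli/hhnet.R grid --out results/
Rscript inst/cli/hhnet.R demo-two-neuron --synapse HS --out results/
```

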