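---
title: "Synchrony and noise robustness in coupled Hodgkin-Huxley networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrony and noise robustness in coupled Hodgkin-Huxley networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhnet)
```

hhnet simulates how synapse type and network topology shape the synchrony
and noise robustness of spiking neuron networks.  A single neuron at the
edge of a network receives a periodic driving current (optionally corrupted
by Gaussian interference), and the questions are: how faithfully does the
rest of the network inherit that drive, how long does the activity take to
propagate, and how much of the interference survives transmission?  The
package answers them with membrane-potential correlations and first-spike
latencies over a grid of coupling models and topologies.

## The neuron model

Each node is a classic Hodgkin-Huxley (HH) membrane: potential $V$ (mV) and
three gating variables $m, h, n \in [0,1]$,

$$C\,\dot V = g_{\mathrm{Na}} m^3 h\,(E_{\mathrm{Na}}-V)
            + g_{\mathrm{K}} n^4\,(E_{\mathrm{K}}-V)
            + g_L\,(E_L-V) + I(t),$$
$$\dot x = \alpha_x(V)\,(1-x) - \beta_x(V)\,x, \qquad x \in \{m,h,n\},$$

with the canonical squid-axon rates shifted so rest sits near $-65$ mV
(`rate_constants()`).  The two activation rates have removable 0/0 points
at $-40$ and $-55$ mV; they are evaluated by their analytic limits within
$10^{-7}$ mV of the singularity, which keeps the field continuous to better
than $10^{-6}$ there.  The inactivation closing rate is the sigmoid
$\beta_h = 1/(e^{-(V+35)/10}+1)$; with it, the steady-state gating point at
$-65$ mV is $(m,h,n) = (0.05293,\ 0.5961,\ 0.3177)$ to four significant
figures, and every simulation starts all neurons exactly there.

Default membrane constants (`hh_params()`): $C = 1\ \mu F/cm^2$,
$g_{\mathrm{Na}} = 120$, $g_{\mathrm{K}} = 36$, $g_L = 0.3$ mS/cm²,
$E_{\mathrm{Na}} = 50$, $E_{\mathrm{K}} = -77$, $E_L = -54.5$ mV.  The
potassium conductance deserves a note: 36 mS/cm² is the only value
consistent with the resting gating point above.  A value an order of
magnitude larger turns the potassium pathway into a shunt that clamps the
membrane near $E_K$ and silences the model entirely — the configuration
parser accepts such values (they are occasionally quoted) but warns.

## The three synapses

All coupling enters the postsynaptic membrane equation as a current
density (`synapse_spec()`):

* **ES (electrical / gap junction).**  $I = g\,(V_{\mathrm{pre}} -
  V_{\mathrm{post}})$, undirected: both endpoints feel equal and opposite
  currents, so an ES edge redistributes charge and injects none (asserted to
  machine precision in the tests).
* **HS (Hansel-type chemical).**  $I = g\,H(V_{\mathrm{pre}}(t-\tau) -
  V_{\mathrm{thresh}})$: a constant current of amplitude $g$ whenever the
  delayed presynaptic potential exceeds the threshold.  $H$ is the
  Heaviside step with $H(0)=0$ (the tie has measure zero on trajectories).
* **RS (Rabinovich-type chemical).**  $I = g\,(V_{\mathrm{rev}} -
  V_{\mathrm{post}})\,H(V_{\mathrm{pre}}(t-\tau) - V_{\mathrm{thresh}})$:
  the same gate, but the delivered current scales with the gap to a
  synaptic reversal potential, i.e. a threshold-gated excitatory
  conductance with postsynaptic feedback.  Written with the drive toward
  $V_{\mathrm{rev}}$ the synapse depolarizes a resting target (6.5
  μA/cm² at $-65$ mV with the defaults) and self-limits as the target
  approaches the reversal point.  The opposite, hyperpolarizing sign
  convention is also seen in print; it cannot propagate threshold-gated
  excitation, so the depolarizing form is the default and the literal
  variant is available as `rs_sign_literal = TRUE`.

Chemical synapses are strictly unidirectional; a neuron with several
afferents receives the algebraic sum of their currents.  Defaults:
$g = 0.1$ (mS/cm² for ES/RS; for HS the gate is dimensionless, so $g$ acts
directly as μA/cm²), $V_{\mathrm{thresh}} = -52$ mV,
$V_{\mathrm{rev}} = 0$ mV.

**The delay $\tau$.**  The chemical models read the presynaptic voltage
$\tau$ ms in the past, realised with per-neuron ring buffers pre-filled
with the resting potential (`delay_buffer()` exposes the same semantics at
the R level).  No biological value is pinned down by the sources this
study draws on; 1 ms is a typical axonal-plus-synaptic latency scale and
is the package default, exposed in the configuration.  Two consequences
are worth knowing before interpreting results: on a directed $N$-ring the
distal first-spike latency is bounded below by $(N-1)\tau$ regardless of
every other parameter, and any fixed per-hop offset of a few ms is enough
to decorrelate raw voltage traces whose spikes are only ~1.5 ms wide
(see "What the tests do and do not show").

**An amplitude caveat for HS.**  With $g$ read as a bare current
amplitude, 0.1 μA/cm² is roughly sixty times below the HH firing
threshold current (~6 μA/cm² sustained), so an HS chain at the network
default cannot re-fire its downstream neurons: activity stops at the first
postsynaptic cell, which shows only a ~0.3 mV ripple.  This is a property
of the model as specified, not of the implementation; the two-neuron
square-wave demonstration therefore defaults to $g = 10$ μA/cm² for HS
(`demo_two_neuron()`), a round value above threshold chosen before any
network run, while ES and RS demos keep $g = 0.1$.

## Topologies

Everything is built on a ring backbone of $N = 100$ neurons, node $i$
feeding $i+1$ and node $N$ closing the loop (`build_ring()`); edges are
directed for chemical synapses and undirected for gap junctions, so the
node farthest from the stimulated neuron 1 is neuron 100 in directed rings
and neuron 50 in undirected ones.  The small-world variant
(`build_nw_hub()`) adds $k = 24$ shortcuts from the stimulated hub to
non-adjacent nodes.  The published figure of the reference topology is not
machine-readable, so the package uses a deterministic, reproducible
default — targets evenly spaced at ring distance 4 (nodes 5, 9, ..., 97) —
and accepts an explicit target list for any other choice.  Hub shortcuts
are directed hub→target (the hub distributes the stimulus); a flag adds
the reverse arcs.  The generic probabilistic construction
(`build_nw_random()`) adds each non-ring pair with probability $p$,
recovering the ring at $p=0$ and the complete graph at $p=1$.

## Stimuli: what the generator emulates — and what it does not

`stimulus_spec()` produces the three study inputs, all applied to neuron 1
only:

* a **square wave**, 10 μA/cm² for the first 10 ms of every 20 ms period
  (the two-neuron validation signal);
* a **sine**, $60\sin(0.1\pi t) + 30$ μA/cm² (20 ms period), strong enough
  to drive bursts of spikes each cycle;
* **sine plus noise**: Gaussian white interference, mean 0, sd 20 μA/cm²,
  drawn once per `noise_sample_dt` and held constant within the interval
  (zero-order hold), seeded and bit-reproducible.

The noise emulates a *sampled interference signal*, not a stochastic
differential: draws are not rescaled by $\sqrt{dt}$.  With the default
`noise_sample_dt` equal to the integration step (0.01 ms), a membrane with
a ~1 ms effective time constant averages ~100 independent draws per time
constant, so the *felt* perturbation is roughly $\mathrm{sd}/10$ and
noise-condition traces differ from their noise-free twins only in the
third decimal.  Hardware or block-diagram noise sources usually hold their
samples for much longer; users who want noise to bite should set
`noise_sample_dt` to the hold interval of the source they are modelling
(e.g. 0.5–1 ms).  The default deliberately stays at the integration step —
that is the study condition this package commits to — and the consequences
for the noise-condition synchrony numbers follow from it.

Real biological noise differs from this generator in ways the tests cannot
probe: channel noise is state-dependent and multiplicative, synaptic
background is correlated in time and across cells, and interference enters
every neuron, not just the stimulated one.

## Integration

`simulate_network()` advances the full $4N$-dimensional state with classic
fixed-step RK4 (forward Euler available), $dt = 0.01$ ms, $T = 300$ ms for
network runs and 100 ms for the two-neuron validation.  The deterministic
stimulus is evaluated analytically at $t$, $t+dt/2$, $t+dt$ for the RK4
stages; delayed presynaptic voltages and the per-step noise draw are held
constant within a step (method-of-steps).  Two engines implement the same
scheme: a compiled core (`src/`) used by default — a 100-neuron, 300 ms
run takes on the order of a second — and a pure-R reference
(`engine = "r"`, built on the exported `step_network()`) kept for
cross-checking; the tests require them to agree to $10^{-9}$ mV and check
the compiled single-neuron path against an independent deSolve RK4
integration to $10^{-8}$ mV.

Numerical choices worth stating:

* **Convergence.**  On smooth vector fields (single neuron, ES coupling)
  halving $dt$ moves no recorded sample by more than 0.5 mV — in practice
  by ~$10^{-3}$ mV.  The chemical Heaviside gate is discontinuous by
  design, so across gate-switch steps the scheme is formally first-order;
  with $dt = 0.01$ ms the induced spike-time jitter is small against the
  1 ms delay but it is the step-size-sensitivity bottleneck.
* **Divergence guard.**  Any non-finite state or $|V| > 150$ mV aborts
  with the neuron index and time, rather than emitting NaNs.
* **Determinism.**  Identical configuration and seeds give bit-identical
  traces; noise-free runs consume no RNG at all.  Every result carries a
  hash of the configuration that produced it, echoed into all CSV output.

## Metrics

`detect_spikes()` takes upward crossings of 0 mV (linearly interpolated,
2 ms refractory) — 0 mV sits far above any subthreshold response, so
detection is insensitive to the threshold within tens of mV.
`correlation_table()` computes the Pearson correlation of raw, full-window
voltage traces for the four reference pairs (1,25), (15,30), (20,35),
(5,45); a `burn_in_ms` option discards an initial transient, but the
default is the full window.  Degenerate traces (a neuron that never left
rest) have no defined correlation and are flagged, never zeroed.
`first_spike_latency()` reports each neuron's first spike relative to the
stimulated neuron, `NA` for silent neurons; a run's window certifies only
a lower bound for those, which is how latency "greater than" claims should
be read.

## What passing tests do and do not show

The acceptance suite runs the full 12-condition grid at study scale and
compares the synchrony tables and latency bounds to their published
counterparts.  Where the comparison is governed by quantities the sources
pin down — the gating fixed point, the two-neuron validation, the ES ring
propagation time to neuron 50 (~100 ms), RS ring synchrony, RS small-world
latency — the pipeline reproduces them within the stated bands.  Where the
outcome hinges on quantities the sources leave open — the delay value, the
exact shortcut set, the representation the correlation was computed on,
and the noise-hold semantics — raw-trace correlations computed under this
package's documented defaults can and do land far from some printed
values, and the corresponding checks are left failing rather than tuned:
the mechanism is the per-hop delay offset described above, which a
correlation on anything slower than raw traces (rates, smoothed
potentials, aligned windows) would not see.

## Limitations

Single-compartment neurons, deterministic channels, one synapse model per
network, noise injected only at the stimulated node, fixed-step
integration without event location, and no plasticity.  The pipeline
measures zero-lag linear synchrony and first-spike latency only; phase
measures and spike-train metrics are out of scope.
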