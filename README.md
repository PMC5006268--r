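# inexsim

Simulation and analysis of spontaneous spiking in maturing in vitro neuronal
networks, as recorded with microelectrode arrays (MEAs).

## The problem

Neuronal cultures differentiated from human embryonic stem cells develop
their activity over weeks: isolated spikes first, then spike trains, then
bursts, as neurons form synapses. MEA recordings capture this maturation as
per-electrode spike trains, but the recordings alone cannot say *why* the
burst structure emerges. `inexsim` implements a minimal phenomenological
model of this process — a network of binary (spike / no spike) neurons whose
connectivity grows over virtual measurement time points — together with the
burst-analysis and calibration machinery needed to compare the simulations
with recordings. It is aimed at computational neuroscientists and MEA labs
who want a controllable in silico counterpart to a maturing culture.

## The model

Time is discretised into slices of Δt = 5 ms (one action potential plus
refractory period, so at most one spike per neuron per slice). Neuron *i*
fires in slice *t_k* with momentary rate

```
lambda_i(t_k) = max(0, c_i + sum_j y_ji * s_j(t_{k-1}))
```

where `c_i >= 0` is its basic (noise-driven) activity, `y_ji` the signed
synaptic strength from neuron *j* (positive for excitatory, negative for
inhibitory presynaptic neurons) and `s_j` the 0/1 spike indicator of the
previous slice. The spike probability in a slice is the inhomogeneous
Poisson one-event probability

```
P_i = (lambda_i * dt) * exp(-lambda_i * dt)   <=  exp(-1)
```

and a spike is emitted when a uniform draw `x_i < P_i`; in the slice
immediately after a spike, `x_i` is multiplied by the history factor
`f = 0.1`, which makes follow-up spikes ~10x more likely and produces
bursts. All parameters (`c_i`, `|y_ji|`) are drawn from triangular
distributions between zero and configurable upper bounds; maturation is
modelled by raising the connection probability from 1% to 10% over six
virtual time points while a brute-force grid search picks the bounds whose
spike and burst rates best match a reference recording.

Bursts are detected with the adaptive cumulative-moving-average (CMA)
method: the CMA of the ISI histogram is summarised, scaled by the ISI
sample's skewness, and the closest-matching histogram bin sets the burst
ISI threshold; three or more consecutive spikes at or below the threshold
form a burst.

## Worked example

One virtual time point at 8% connectivity (the fifth maturation stage) with
the published bounds, analysed like a 9-electrode well:

```r
library(inexsim)
net <- generate_network(network_spec(
  n_neurons = 1000, connection_probability = 0.08,
  bounds = parameter_bounds(0.09, 0.5, -0.1), seed = 1))
net
#> <inex_network> 1000 neurons (200 inhibitory), 80490 connections (density 0.0806)

sts <- simulate_network(net, simulation_config(duration_s = 300), seed = 1)
sts
#> <spike_train_set> 1000 units, 300 s, 20272 spikes (4.05 spikes/min/unit)

feats <- analyze_spike_trains(subset_units(sts, 0:8))
feats
#>   unit_id spike_rate burst_rate burst_duration_s spikes_per_burst n_bursts
#> 1       0        7.4        0.6           17.180             7.00        3
#> 2       1        1.2        0.2            0.775             3.00        1
#> 3       2        4.8        1.0           12.249             4.00        5
#> 4       3        1.0        0.0               NA               NA        0
#> 5       4        1.8        0.4           34.035             4.00        2
#> ...

summarize_quartiles(feats$spike_rate)
#>  q1   m  q3
#> 1.8 4.6 5.0
```

`spike_rate` is in spikes/min per unit, `burst_rate` in bursts/min; unit 3
had no bursts, so its burst-structure features are absent (`NA`), not zero.
The full maturation experiment (six time points, ten 300-s runs each,
quartiles of the pooled first nine units, comparison against the embedded
MEA reference table) is one call:

```r
m <- run_maturation(maturation_schedule(), seed = 1)
m$summaries      # quartiles per time point and feature
m$report         # simulated medians vs reference interquartile ranges
```

A command-line interface covering `simulate`, `analyze`, `search`,
`maturation`, `fixtures` and `report` is available through `inex_cli()` or
the `inst/scripts/inex` launcher.

Note: the time units of `lambda` are not fixed by the model equations; the
convention (per second, per slice, per millisecond) is an explicit,
recorded configuration choice, and `calibrate_conventions()` scores the
candidates against the reference data. See the methods vignette
(`vignettes/inexsim-methods.Rmd`) for this and every other numerical
choice.

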