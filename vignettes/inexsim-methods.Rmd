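---
title: "Methods: the inexsim model, its conventions and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the inexsim model, its conventions and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`inexsim` simulates spontaneous activity of a cultured neuronal network as a
cellular automaton of binary neurons on a fixed time grid. In every slice of
length Δt each neuron *i* carries a momentary rate

    lambda_i(t_k) = max(0, c_i + sum_j y_ji * s_j(t_{k-1}))

built from its basic activity `c_i` (a catch-all for noise sources that make
isolated neurons fire) and the signed strengths `y_ji` of the presynaptic
neurons that spiked in the *previous* slice. The spike probability of the
slice is the one-event probability of an inhomogeneous Poisson process,

    P_i = (lambda_i * dt) * exp(-lambda_i * dt),

and the neuron fires when a fresh uniform draw `x_i` falls below `P_i`.

Assumptions worth making explicit:

* **Synchronous updates.** All neurons read the same previous-slice spike
  vector; there are no transmission delays.
* **At most one spike per slice.** Δt = 5 ms is chosen to cover an action
  potential plus its refractory period, so the binary-per-slice coding is
  the refractory model.
* **Silent start.** Simulations begin with no spikes in the (virtual)
  previous slice — the least-assumption choice for a culture on the day of
  plating.
* **Non-monotone hazard.** `x * exp(-x)` peaks at `exp(-1)` when
  `lambda * dt = 1` and *decreases* beyond it, so extremely strong summed
  input quenches rather than saturates activity. This is a property of the
  model, not of the implementation.
* **One-slice multiplicative facilitation.** After a spike, the neuron's
  next uniform draw is multiplied by the history factor `f` ("the draw
  decreases by factor f"), which multiplies the post-spike firing chance by
  up to `1/f`. We read the factor as multiplicative because an additive
  reading would put a floor of about `f` on every post-spike probability,
  which is incompatible with the very low rates observed at the first
  maturation stage. Facilitation lasts exactly one slice and is re-armed by
  each spike; it is not a model of short-term plasticity.

## Networks

Networks are directed and random: every ordered pair (j, i), j ≠ i, is
connected independently with the stage's connection probability (autapses
never occur, matching the biology of the modelled cultures). A fixed
`round(n * fraction)` subset of neurons is inhibitory — deterministic rather
than Bernoulli so the canonical 800/200 split of a 1000-neuron network is
exact and reproducible. Outgoing weights carry the sign of the presynaptic
type. All magnitudes — `c_i` and `|y_ji|` — are drawn from triangular
distributions on `[0, bound]`.

**Triangular mode.** Only the bounds of the triangular distributions are
documented in the source material, never the mode. The package defaults to
mode = bound (`triangular_mode_fraction = 1`), which keeps the "upper
boundary" the most likely value; the mode is a configurable calibration
degree of freedom (0, 0.5, 1 are scored by `calibrate_conventions()`).

**Per-stage redraw.** The maturation description is internally ambiguous:
connections are "redefined" at every stage, yet only the *addition* of
connections is biologically allowed. We redraw every stage's network
independently (the "redefined" reading): with i.i.d. edges and per-edge
strengths, a fresh draw at higher density is statistically indistinguishable
from a superset draw for every analysis the package performs, and it keeps
the stages exchangeable. A superset mode was considered and rejected as
added state for no measurable difference.

## Time-unit convention of the rate

The rate equation multiplies `lambda` by Δt without fixing units, and the
published parameter values (c around 0.07–0.09, y around 0.1–0.5) cannot be
mapped to physical rates unambiguously. The package therefore makes the
convention explicit and records it in every output's provenance:

| convention        | `dt_eff` | meaning of `c = 0.07`        |
|-------------------|----------|------------------------------|
| `per_second`      | 0.005    | 0.07 spikes/s ≈ 4 spikes/min |
| `per_slice`       | 1        | 0.07 spikes/slice ≈ 14 /s    |
| `per_millisecond` | 5        | 0.07 spikes/ms (very high)   |

`calibrate_conventions()` scores each candidate convention (crossed with
the triangular-mode candidates) by simulating the first and fifth
maturation stages with the published bounds and measuring the spike/burst
rate loss against the experimental reference quartiles; the argmin is
returned with full diagnostics instead of being hard-coded. The default is
`per_second`, the only convention whose baseline rates have the same order
of magnitude as the sparse first-stage recordings.

**Known discrepancy.** Under none of the three candidate conventions do the
re-simulated rates reproduce the *published simulated* (INEX reference
rows) medians within stochastic tolerance — `per_second` undershoots
(roughly 4 vs 11 spikes/min at stage 1) and the other two conventions
overshoot by orders of magnitude. The acceptance test that asserts this
reproduction is therefore expected to stay red; it is kept, rather than
loosened, because it documents exactly which under-specified conventions
block quantitative reproduction. All structural claims (rates rising to
stage 5 and dropping at stage 6, in-range behaviour of the search) are
reproduced and tested independently of the convention.

## Burst detection

The adaptive threshold works on the ISI histogram of each unit separately:

1. histogram of ISIs in fixed bins of 5 ms (= Δt, the finest ISI the
   simulator can produce; configurable; the source material names no width);
2. cumulative moving average `CMA[k] = mean(counts[1..k])`;
3. `CMA_m` = the *mean* of the CMA curve (the original tool used the
   maximum; both are available via `cma_stat`, the text of the modelled
   study says mean, and that is the default — the discrepancy is surfaced
   as an option, not silently resolved);
4. `alpha` = Fisher–Pearson skewness of the *raw* ISI sample (default
   `alpha_mode = "raw"`; a clamped-coefficient variant into [0.3, 1] is
   available);
5. threshold = the right edge of the bin whose CMA value is closest to
   `alpha * CMA_m`, ties toward the smaller ISI (conservative bursts).
   "Closest" is computed on the CMA (counts) scale; the dimensionally
   literal alternative — reading `alpha * CMA_m` as seconds and snapping to
   the nearest observed ISI — is available via `semantics = "literal"`.

Bursts are maximal runs of spikes whose successive ISIs are all at or below
the threshold, kept if they contain at least 3 spikes; burst duration is
last spike minus first spike. Units with fewer than 4 spikes skip burst
analysis entirely (they cannot contain a 3-spike burst with a meaningful
adaptive threshold); their spike rate is still reported.

**Absent vs zero.** For a unit without bursts the burst *rate* is reported
as 0 (a genuine observation), while burst *duration* and *spikes per burst*
are `NA` — a zero-length burst is undefined. Quartile pooling drops `NA`s,
so burst-structure quartiles summarise bursting units only.

## Feature statistics

The four features are spike rate (spikes/min), burst rate (bursts/min),
mean burst duration (s) and mean spikes per burst. Stage summaries pool the
per-unit values of the first 9 units of every run (10 runs × 9 units = 90
values) and report Q1/median/Q3 by linear interpolation between closest
ranks (R's type-7 quantile, the default of mainstream numeric stacks; the
source material names none). Pooling is single-stage — quartiles over the
90 values, not over per-run medians — because the reference analysis
describes no two-stage summary.

Channel/well filtering mirrors the experimental rules: a channel is
inactive when its spike rate at its last measured time point is strictly
below 20 spikes/min; a well with fewer than two active channels is dropped;
wells are classed by their stage-5 mean spike rate as low (< 50), medium
(50–250, both ends closed) or high (> 250 spikes/min). The embedded
reference table holds the medium-activity quartiles.

## Brute-force search and its seeds

The default grid is the published one: c ∈ {0.01, …, 0.09},
y⁺ ∈ {0.1, …, 0.9}, y⁻ ∈ {−0.1, …, −0.9}; 729 candidates enumerated
c-major. The objective is the summed relative deviation of the spike- and
burst-rate medians from the reference medians, with candidates whose
medians fall inside the reference interquartile ranges preferred outright
("approximately in range" first, distance second). Every candidate is
simulated with the *same* per-run substream seeds spawned from one master
seed, so candidates are compared under paired noise and the whole search
replays exactly. `runs_per_candidate` defaults to 1 — the selection signal
is strong relative to run-to-run noise and a 729-point grid at ten runs
each would be needless for picking a winner; the chosen bounds can then be
re-run at the full ten-run protocol.

The parameter-recovery acceptance check builds a synthetic reference by
simulating known bounds at reduced scale (200 neurons, 60 s) and verifies
the search places those bounds in the loss top-decile of the grid. It runs
under the `per_slice` convention with sparse (2%) connectivity and a weak
generating excitatory bound: in that regime rates respond sharply to the
basic-activity bound, while stronger excitatory candidates tip the dynamics
into runaway self-excitation (see the bistability note below) and are
cleanly rejected by distance. The check exercises the search machinery; it
is not a statement about which convention matches the biology.

**Bistability of the strong-coupling conventions.** Because post-spike
facilitation divides the uniform draw by `1/f = 10`, any neuron whose spike
probability exceeds `f` re-fires with certainty in the next slice. Under
the `per_slice` and `per_millisecond` conventions this condition is met
across most of the parameter range, so a single spike can lock a neuron —
and, through its targets, the whole connected component — into a permanent
full-rate state. This absorbing state is a property of the model equations
under those unit readings, and is one more reason `per_second` (where
`P << f` everywhere) is the default convention.

## What the synthetic fixtures do and do not establish

`generate_bursty_fixture()` plants rigid bursts (fixed intra-burst ISI,
fixed spike count, gaps at least 1 s) on top of optional homogeneous
Poisson background spikes, and returns the ground truth alongside. Recovery
of ≥ 90% of planted bursts establishes that the threshold/detection
pipeline finds unambiguous burst structure and never violates its own rules
— it does not establish detector performance on real recordings, which have
drifting rates, overlapping time scales, electrode noise and no ground
truth. Likewise, the maturing-network trend test establishes that the model
reproduces the qualitative rise-then-drop of spike and burst rates, not
that any specific printed rate is matched (see the convention discrepancy
above).

## Numerical choices and degenerate inputs

* ISIs landing exactly on a bin edge are assigned to the bin whose right
  edge they equal (a 9-digit rounding guard absorbs floating-point error).
* A single-bin ISI histogram returns that bin's ISI as the threshold; fewer
  than two spikes yield an empty-histogram sentinel and no burst analysis.
* Quartile summaries of all-`NA` vectors are `NA`, not an error; the
  reference comparison reports missing time points as absent rows.
* A zero reference median switches that objective term from relative to
  absolute deviation.
* Spike times are slice starts; simultaneous spikes across units are
  by construction, within a unit impossible.
* All RNG flows through R's generator (including inside the compiled core),
  so a single integer seed reproduces networks, simulations, searches and
  maturation reports bit-for-bit.

## Known limitations

* No transmission delays, no refractoriness beyond the slice, no short- or
  long-term plasticity, no spatial topology, apoptosis or proliferation —
  all outside the model family by design.
* Synapse pruning appears only as reduced strengths/probabilities between
  stages, never as explicit edge removal within a simulation.
* Network-wide synchronous population bursts are not detected or modelled;
  the burst detector is per-unit.
* The published simulated rates are not quantitatively reproduced under any
  candidate unit convention (documented above and enforced by a
  deliberately red acceptance test).
* With 300-s recordings the per-unit burst rate is quantised in steps of
  0.2 bursts/min, so a pooled burst-rate *median* cannot resolve relative
  changes smaller than one quantum. Under the default convention the
  final-stage activity drop is sub-quantum: the spike-rate median falls at
  the last stage as in the recordings, but the burst-rate median stays on
  its lattice point (a second deliberately red acceptance assertion).
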