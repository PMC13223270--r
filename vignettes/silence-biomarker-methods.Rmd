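---
title: "Neuronal silence as a seizure biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal silence as a seizure biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

silencenet simulates intermittent seizure-like synchronization in
conductance-based spiking networks, measures it with spike-train biomarkers,
predicts imminent synchronized (up) states from prolonged network silence,
and suppresses them with a closed-loop stimulation controller. This vignette
documents the model, the metrics, the numerical choices, and the design
decisions that were genuinely open, together with what the test suite does
and does not establish.

## The network model

Every neuron follows a single-compartment conductance-based membrane
equation

$$ C \frac{dV_i}{dt} = -g_\mathrm{leak}(V_i - E_\mathrm{leak})
  + I_\mathrm{Na}^i + I_\mathrm{K}^i + I_\mathrm{M}^i
  + I_\mathrm{ext} + I_\mathrm{sup}^i
  + \sum_j (V^\mathrm{rev}_j - V_i)\, g_j M_{ij}, $$

with every ionic current written in driving-force form
$g\,\cdot\,\mathrm{gate}\,\cdot\,(E - V)$, so that potassium-type currents
always hyperpolarize. $I_\mathrm{Na} = g_\mathrm{Na} m^3 h (E_\mathrm{Na}-V)$
and $I_\mathrm{K} = g_\mathrm{K} n^4 (E_\mathrm{K}-V)$ use the Traub-style
rate functions for regular-spiking cortical cells, shifted by a threshold
parameter $V_T$. The slow potassium (M-type) current
$I_\mathrm{M} = g_\mathrm{M}\, p\, (E_\mathrm{K}-V)$ adapts firing: its gate
relaxes to a sigmoidal $p_\infty(V)$ (midpoint $-35$ mV, slope 10 mV) with a
bell-shaped time constant scaled by `tau_max`. During sustained firing $p$
accumulates and curbs excitability; during silence $p$ decays (near rest its
time constant is roughly `tau_max`/12), lowering adaptation and priming the
population for synchronized burst discharge. This decay-during-silence loop
is the mechanism that links prolonged network silence to up-state onset, and
it is why the mean silence time works as a predictor.

Synapses are conductance jumps: when neuron $j$ crosses 0 mV upward, its
single outgoing conductance $g_j$ jumps by `g_syn` (excitatory cells) or
`inh_weight_factor * g_syn` = 4 `g_syn` (inhibitory cells) and then decays as
$dg_j/dt = -g_j/\tau_s$. Excitatory synapses drive toward 0 mV, inhibitory
toward $-80$ mV. The standard network is an Erdős–Rényi graph of
$N = 1000$ neurons (80% excitatory) with connection probability $p = 0.1$
and no self-connections.

### Units and the calibration anchor

The model mixes literature conventions: conductances are per-area
(mS/cm², with `g_syn` quoted in μS/cm²) while injected currents are
quoted in pA. Internally everything lives in one coherent system (mV, ms,
μF/cm², mS/cm², μA/cm²); a single factor `current_scale` (μA/cm² per pA,
default 0.008) converts the quoted `I_ext` = 175 pA and the stimulation
amplitude into current densities. Two constants were deliberately left as
calibration degrees of freedom, because the regular-spiking channel
formulation fixes neither: `current_scale` and the synaptic decay `tau_s`
(default 5.7 ms). They were fixed **once**, against a single anchor: the
1000-neuron network must cross from asynchronous spiking (global CV < 0.5)
to synchronized bursting (CV ≥ 0.5) near `g_syn` ≈ 1.8 μS/cm², with
intermittent alternation between the two regimes just above the transition
(1.81–1.84) — long up states of tens of seconds, down states whose network
mean silence time stays below ~120 ms, and pre-onset silences a few hundred
milliseconds long. All other channel constants keep their regular-spiking
defaults (`g_Na` 56, `g_K` 6, `g_M` 0.09 mS/cm², `E_Na` 50, `E_K` −90 mV,
`V_T` −56.2 mV, `tau_max` 1000 ms).

### Numerics

Integration is fixed-step classical RK4 (default `dt` = 0.05 ms) on the
five-dimensional per-neuron state $(V, m, h, n, p)$; the voltage-dependent
rate functions are tabulated on a 0.05 mV grid and linearly interpolated.
Synaptic conductances decay analytically within a step (exact exponential
stage factors) and jumps are applied at step boundaries. Spikes are upward
crossings of 0 mV with a 1 ms lockout so one action potential is never
counted twice. Initial voltages are drawn uniformly on
[`E_leak`, −20 mV] from the run's seed; gates start at their
voltage-dependent steady state; everything downstream is deterministic, so
two runs with the same (topology, parameters, dt, seed) are bit-identical.
A guard aborts integration with an informative error if |V| exceeds 500 mV.
Tiny conductances are flushed to zero at 1e−30 so long silences never
enter subnormal arithmetic. Halving `dt` changes a 1 s single-neuron spike
count by at most one spike; network statistics at `dt` = 0.05 ms are well
inside their seed-to-seed variability.

## Biomarkers

All metrics are computed from spike times only, on a uniform grid
(default 1 ms):

- **Kuramoto order parameter** $R(t)$: each neuron's phase advances by
  $2\pi$ per interspike interval, linearly interpolated,
  $\varphi_j(t) = 2\pi m + 2\pi (t - t_j^m)/(t_j^{m+1} - t_j^m)$; then
  $R(t) = |\sum_j e^{i\varphi_j}| / N_\mathrm{defined}$. Phases are masked
  before a neuron's first and after its last spike. $R \in [0, 1]$.
- **Global CV**: the network mean ISI averages per-neuron mean ISIs; the ISI
  standard deviation is taken over the pooled ISI multiset (population
  denominator; a per-neuron mode is available since the pooling convention
  is a genuine choice). CV ≥ 0.5 classifies bursting, CV < 0.5 tonic
  spiking.
- **Instantaneous CV(t)**: per neuron, the CV of the 14 consecutive ISIs
  surrounding $t$ (7 ending at or before the spike preceding $t$, 7
  following, including the interval containing $t$), averaged over neurons
  with defined values. Including the current interval matters: it is what
  lets CV(t) rise during the pre-onset silence and inside bursts. A pooled
  variant exists.
- **Mean silence time** $\langle T \rangle(t)$: the average over all
  neurons of the elapsed time since each neuron's last spike, with silence
  measured from the recording start before a neuron's first spike (maskable).
  This is the prediction biomarker.

**State segmentation**: a time point is *up* iff CV(t) ≥ 0.5 and
R(t) ≥ 0.6, else *down* (masked points count as down); runs shorter than the
debounce dwell (default 200 ms) are merged into their surroundings. The
debounce suppresses threshold flicker at state edges without hiding any
state the model actually dwells in.

**ISI return map**: points $(\mathrm{ISI}_n, \mathrm{ISI}_{n+1})$ with the
instantaneous CV at the shared spike, labelled by rule — both ISIs in the
regular band [50, 90] ms with CV < 0.5 (sustained down state); both in the
short band [10, 40] ms with CV ≥ 0.5 (active burst); short→long
(interburst transition); long→short (pre-burst); otherwise unassigned.
Band edges are configurable.

## Prediction

The **threshold predictor** emits an event when $\langle T \rangle$ crosses
120 ms upward (refractory 1 s between events). Events are matched to the
next up-state onset within a 2 s horizon: the first event per onset is a hit
with lead time $\tau$ = onset − crossing; later events for the same onset
are deduplicated; events with no onset in reach are false alarms. The
prediction threshold (120 ms) and the suppression trigger (100 ms) are
distinct named parameters and are never shared. The matching horizon,
refractory, and deduplication rule were unspecified design territory; the
defaults (2 s, 1 s, first-event-wins) are documented here and configurable.
Two deduplication readings exist when several crossings precede one onset:
`"first"` keeps the earliest alarm (what a deployed alarm system would
report) and `"closest"` keeps the most recent crossing before the onset —
the silence episode directly preceding the transition, which is the lead
time the biomarker analyses quote. With `refractory = 0` and
`dedup = "closest"` the reported lead time is exactly
onset − (last prior upward crossing of the threshold).

The **forest forecaster** regresses R(t) on the two lagged features
$\langle T \rangle(t - \mathrm{lag})$ and $\langle T \rangle(t - 2\,
\mathrm{lag})$ (lag 10 ms) with a 200-tree random forest. The split is
contiguous in time — the first half trains, the rest tests — and
hyperparameters (maximum depth 0/6/12, minimum node size 5/25) are chosen by
5-fold cross-validation on contiguous blocks of the training window, so no
feature row ever sees future targets. Forest fitting is delegated to the
`ranger` package with a fixed seed and one thread for reproducibility.

## Closed-loop suppression

During a controlled run the integrator maintains the network mean silence
time online from its own last-spike table (same first-spike convention as
the offline metric). When it crosses the trigger (default 100 ms) upward and
the controller is armed, a constant depolarizing current `I_sup` (default
210 pA, converted by the same `current_scale`) is injected into the target
set for `t_sup` (default 4 s), after which the controller stays disarmed for
a 1 s cooldown. The rearm policy was unstated design territory; triggering
is silence-based, and since silence collapses at up-state onset, triggers
inside ongoing up states are rare. Targets are either a random 1% of the
excitatory population or every (optionally also inhibitory) neuron within a
radius of an electrode position. With `I_sup` = 0 or an empty target set the
controller provably does not perturb the numerics: spike output is
bit-identical to an uncontrolled run.

Condition comparisons use the two-sided Mann–Whitney U test with the
rank-biserial effect size $r_{rb} = 1 - 2U/(n_a n_b)$; the percent reduction
defaults to the mean up-state duration, with the median and maximum reported
alongside, because a single summary hides the tail behavior that matters
clinically (maximum durations).

## Surrogate data

The surrogate generator emulates only spike-time statistics, never the
biophysics: labelled epochs of Poisson firing (down), programmed silence,
and synchronized bursting with per-unit onset jitter (up), with the ground
truth returned alongside. The default burst pattern (8 bursts/s, 4 spikes
per burst, 15 ms intra-burst ISI, 1 ms jitter) keeps within-burst intervals
inside the short interburst band and between-burst gaps below both silence
thresholds, so surrogate up states read as sustained bursting to every
metric. Surrogates let the predictor, classifier and recordings analyses be
tested end-to-end against known truth; passing those tests establishes the
correctness of the metrics and the plumbing, *not* that real recordings
contain the silence biomarker — that claim rests on the simulations and on
onset-aligned analyses of sorted multiunit data.

## Problem sizes used by the checks

Full-scale studies of this model run thousands of seconds; the packaged
acceptance analyses use desk-scale versions chosen as the smallest sizes at
which each effect is reliably measurable: 9-point coupling sweeps of 15 s
(after a 5 s transient), 50–130 s intermittency runs at couplings
1.811–1.835 (the longest at 1.83, where the longest up states are measured),
and 70–100 s closed-loop runs at matched seeds. The standard network is one
fixed-seed Erdős–Rényi realization used throughout (the intermittent window
shifts slightly between graph realizations); run-level randomness (initial
conditions, target sampling, forest) is seeded per analysis. At these sizes
up-state counts per run are in the tens, so duration summaries carry
sampling error of order 10–20%; the tests assert accordingly.

## Known limitations

- The intermittent regime is narrow in `g_syn` (roughly 1.80–1.85 at the
  default calibration), as expected near a synchronization transition;
  quantitative dwell-time statistics are sensitive to seed and network
  realization.
- At the default calibration the near-transition dynamics are organized
  around a slow volley rhythm: population bursts recur every ~250 ms in both
  states, and the mean-silence-time excursions between volleys peak near the
  120 ms prediction threshold rather than far below it. Threshold crossings
  therefore occur sporadically throughout the rhythm, not exclusively in a
  single prolonged pre-onset silence, and the lead time between the last
  crossing and a classified up-state onset is typically several volley
  cycles (~0.4–0.9 s median) rather than tenths of that. Calibrations with
  faster adaptation recovery (`tau_max` near 600 ms) suppress the spurious
  crossings but then no silence ever reaches 120 ms, and the threshold
  predictor emits no events at all; within the explored calibration family
  a regime combining tens-of-seconds up states with a cleanly separated
  >120 ms pre-onset silence was not found. Lead-time statistics from this
  package should be read with that structure in mind.
- Single-compartment neurons, one synaptic time constant, no conduction
  delays, no plasticity, no gap junctions; stimulation is a constant
  current, not a charge-balanced pulse train.
- The spike-table reader consumes already-sorted spike times; spike sorting
  and LFP processing are out of scope.
- Up/down segmentation inherits the CV window length: state edges are only
  defined to within the span of the surrounding 14 ISIs, which is why
  ground-truth recovery is asserted to the debounce scale, not to the
  millisecond.
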