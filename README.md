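# silencenet

Seizure-like synchronization in spiking neuronal networks: simulation,
silence-based prediction, and closed-loop suppression.

## The problem

Epileptic seizures correspond to episodes of abnormal synchronized bursting
in neuronal networks. In conductance-based network models poised near the
synchronization transition, asynchronous spiking ("down" states, the healthy
regime) alternates spontaneously with synchronized bursting ("up" states,
the seizure-like regime). A robust early-warning signal for the down-to-up
transition is a *prolonged period of network silence*: when most neurons
have been quiet for unusually long, the slow potassium (M-type) adaptation
current decays, the population loses its brake, and the next volley recruits
the whole network into synchronized bursting.

silencenet is for computational neuroscientists and neuroengineers who want
to study this mechanism quantitatively: it simulates the network, measures
the biomarker, evaluates prediction quality, and closes the loop with a
stimulation controller that acts on predicted up states. The same biomarker
machinery applies directly to sorted multiunit recordings.

## The model and the biomarker

Each of N = 1000 neurons (80% excitatory, Erdős–Rényi connectivity,
p = 0.1) follows

    C dV/dt = -g_leak (V - E_leak) + I_Na + I_K + I_M + I_ext + I_sup
              + Σ_j (V_rev(j) - V) g_j M_ij

with Hodgkin–Huxley sodium/potassium spike currents, a slow M-type potassium
current providing spike-frequency adaptation, and conductance-jump synapses:
when neuron j spikes, its outgoing conductance jumps by `g_syn` (excitatory)
or `4 g_syn` (inhibitory), then decays with time constant `tau_s`. Sweeping
the coupling `g_syn` moves the network from asynchronous spiking to
synchronized bursting, with intermittent alternation near the transition
(`g_syn` ≈ 1.8 μS/cm²).

From spike times alone the package computes, on a common time grid:

- `R(t)` — Kuramoto order parameter over interpolated spike phases
  (1 = fully synchronized);
- `CV(t)` — instantaneous interspike-interval coefficient of variation
  (14 surrounding ISIs; ≥ 0.5 indicates bursting);
- `⟨T⟩(t)` — **mean silence time**, the network average of the elapsed time
  since each neuron's last spike: the prediction biomarker.

Up states are segments with `CV(t) ≥ 0.5` and `R(t) ≥ 0.6`. An up state is
predicted when `⟨T⟩` crosses 120 ms; the closed-loop controller triggers at
100 ms and injects `I_sup` = 210 pA into 1% of the excitatory neurons for
4 s. A 200-tree random forest regressing `R(t)` on `⟨T⟩(t−10 ms)` and
`⟨T⟩(t−20 ms)` quantifies how much synchrony information the silence time
carries.

## Worked example

```r
library(silencenet)

topo <- build_er_topology(1000, p = 0.1, frac_excitatory = 0.8, seed = 42)
run  <- intermittency_run(topo, g_syn = 1.83, duration = 60000, seed = 2)
print(run)
#> intermittency run at g_syn = 1.83 (seed 2): 9 up state(s)
#>   up durations (s): 18.6 8.6 6.0 6.0 6.0 3.7 3.5 1.9 0.9

# predict up states from the mean silence time
ev <- threshold_predict(run$series, threshold = 120, refractory = 0,
                        segments = run$segments, dedup = "closest")
lead_time_stats(ev)$median
#> [1] 658

# close the loop: silence-triggered stimulation of 1% of excitatory neurons
sup <- intermittency_run(topo, g_syn = 1.83, duration = 60000, seed = 2,
                         controller = stim_protocol())
compare_conditions(run$up_durations, sup$up_durations)
#> condition comparison (n = 9 vs 29)
#>   mean duration: 6.13 s vs 1.04 s (83.0% reduction)
#>   Mann-Whitney U = 245, p = 8.431e-05, rank-biserial = -0.877
```

The run alternates spontaneously between asynchronous spiking and
seizure-like up states lasting up to tens of seconds; the silence biomarker
crosses its 120 ms threshold a fraction of a second before each classified
up-state onset (the methods vignette discusses why the lead times sit at the
volley-rhythm scale in this calibration); and with the controller enabled
every up state is cut to about a second — an 83% reduction of the mean
duration in this short window, and over 90% for the longest events in longer
runs.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli/silencenet", package = "silencenet"))') \
    simulate --duration 20000 --seed 7 --out run.tsv
```

Subcommands: `simulate`, `analyze`, `predict`, `suppress`, `recordings`,
`fixtures`. Spike tables are plain TSV (`unit_id<TAB>time_s`), topologies a
documented TSV node/edge format, configs YAML.
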