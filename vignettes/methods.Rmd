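---
title: "Modeling evoked gamma entrainment deficits: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling evoked gamma entrainment deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Patients with schizophrenia reliably show a reduced auditory steady-state
response (ASSR) at 40 Hz: when driven by 40 Hz click trains, their EEG power
at 40 Hz is lower than in controls, while the response to 30 Hz drive is
intact and power at 20 Hz (the subharmonic of the 40 Hz drive) is often
increased. `szgamma` models this endophenotype with a conductance-based
excitatory/inhibitory spiking network of primary auditory cortex, and asks a
multifactoriality question: is the "SZ-like" network phenotype driven by one
GABAergic parameter, or only by combinations of parameters?

The workflow has four layers:

1. a spiking network (pyramidal and basket cells on lattices, dual-
   exponential synapses, periodic click-train drive, Poisson background);
2. a simulated EEG — the sum of all excitatory postsynaptic currents (EPSCs)
   arriving at excitatory cells — analyzed by FFT periodogram and band-power
   extraction at 20/30/40 Hz;
3. three illness metrics over a six-dimensional grid of GABAergic
   abnormalities, with a 30 Hz validity gate;
4. a normalized-mutual-information (nMI) analysis over all parameter
   subsets, quantifying how much single parameters versus combinations
   predict the phenotype.

## Network model

Excitatory cells sit on a 24 x 24 lattice (unit spacing), inhibitory cells
on a 12 x 12 lattice spanning the same extent (double spacing, offset to
center). Connection probability decays exponentially with Euclidean
distance, `p(d) = c exp(-d / lambda)` with `lambda = 4` grid units by
default; `c` is normalized so the average probability over all ordered pairs
of a pathway equals the pathway's base probability (0.15 E->E, 0.45 E->I,
0.6 I->E, 0.6 I->I). For dense pathways the naive constant would exceed 1 at
short distances, so `c` is re-solved on the clipped form — the population
average is preserved exactly and expected synapse counts are independent of
`lambda`. Weights are fixed independent of distance. Open boundaries (a
cortical patch), independent Bernoulli draws per ordered pair, no
self-connections.

Synapses are peak-normalized dual exponentials; the default parameter
table gives, per pathway, probability, peak conductance, rise and decay
times (e.g. I->E: 0.6 / 0.6 nS / 1 ms / 6 ms; thalamic->E: 1.0 / 50 nS /
1 ms / 3 ms). Reversal potentials are 0 mV (excitatory) and -75 mV (GABA-A);
recurrent connections carry a uniform 0.5 ms delay. All of these are
configuration, not code constants.

### Cell models

The detailed auditory-cortex models this network descends from use
multicompartment cells whose channel kinetics are spread across a prior
literature. We use reduced cells instead, calibrated to the qualitative
firing phenotypes that matter for the population rhythm:

* **Pyramidal (excitatory)**: four compartments — soma, proximal apical
  (thalamic synapse), distal apical (recurrent excitation), basal
  (background noise) — with RTM (reduced Traub–Miles) Na/K_dr kinetics plus
  a high-threshold Ca current and a calcium-gated K_AHP on the soma. Under
  constant current it fires regularly with spike-frequency adaptation
  (non-decreasing interspike intervals).
* **Basket (inhibitory)**: soma plus a single cylindrical dendrite carrying
  all synapses, with Wang–Buzsáki fast-spiking kinetics: sustained
  high-rate, non-adapting firing (ISI coefficient of variation < 0.1). Like
  the original interneuron model it shows depolarization block far above
  its operating range; calibration and tests stay inside that range.

**Synaptic attenuation.** Each compartment carries a `syn_attenuation`
factor scaling the conductance of synapses it receives. This is the standard
price of collapsing a large dendritic tree into one or two compartments: in
the detailed morphology, tens of convergent ~30 nS synapses are distributed
over a tree with substantial local conductance load, whereas a small reduced
compartment would be clamped to the excitatory reversal by the same input
(saturating both the dynamics and the recorded EPSCs, and — importantly —
inverting the effect of inhibition on the simulated EEG: with a saturated
dendrite, suppressing excitatory firing *raises* apparent thalamic EPSC
amplitude). Defaults (thalamic 0.25, recurrent-E 0.12, elsewhere 1) were
calibrated once, against three targets: spontaneous rates of ~1–5 Hz (E) and
~5–15 Hz (I) under 10 Hz background drive; a clean spectral peak at the
drive frequency for both 30 and 40 Hz click trains; and the inhibition-veto
mechanism (prolonged I->E decay able to suppress the click response). They
were frozen before the acceptance thresholds were evaluated and are exposed
as configuration.

The thalamic synapse sits on its own proximal apical compartment rather than
sharing the recurrent-excitation compartment. The split is anatomically
motivated (the thalamic synapse is proximal and electrotonically close; the
recurrent synapses are distributed) and dynamically necessary: the two
input streams need different attenuation, because the recurrent stream is
~20-fold convergent while the thalamic stream is a single synapse.

### Integration

Exact exponential-Euler updates for channel gating (via voltage-indexed
lookup tables of `x_inf` and `exp(-dt/tau)`), with a semi-implicit
Crank–Nicolson voltage update by default (an explicit exponential-Euler
variant is available). The default step is `dt = 0.02` ms — the conventional
step for models of this class. Spikes are upward crossings of -20 mV with a
2 ms lockout. Synapses aggregate per (pathway, postsynaptic cell) into two
exactly-decayed state variables; spike propagation uses per-pathway ring
buffers (uniform 0.5 ms delay). Runs are bit-reproducible from the
configuration seeds; the C++ core contains no random numbers.

## Stimulation

A Poisson-rate drive cannot produce the sharp spectral entrainment peaks
of the click-train paradigm unless the train is shared and effectively
periodic; periodic shared click trains are also the standard ASSR paradigm
of the EEG/MEG literature being modeled. The default
is therefore **periodic + shared** (every cell receives the identical
train), with Poisson and per-cell-independent modes retained as options.
Clicks reach every excitatory cell and a random 65% of inhibitory cells;
background is independent 10 Hz Poisson per excitatory cell only.

## Simulated EEG and spectra

The EEG is the sum over excitatory cells of every excitatory-category
synaptic current (recurrent E->E, thalamic, background), averaged within
1 ms sample bins (1 kHz, standard EEG practice); larger values mean more
excitatory current. Spectra are plain rectangular-window periodograms of the
mean-subtracted signal, normalized so powers sum to the time-domain
variance. "The component at f Hz" is the band sum within +/-1.5 Hz of f — a
single-bin readout is fragile under leakage, and 1.5 Hz still separates
20/30/40 Hz cleanly. The first 1000 ms (500 ms at mini scale) are discarded
as onset transient. Stimulus-locked averages cut the post-transient EEG into
two-cycle segments aligned to every second click (first post-transient click
fixes the parity; figures depend on this only up to a phase) and average
pointwise; spike histograms bin spike phases over the same segments.

## Illness metrics

With `P40`/`P20` the 40/20 Hz components under 40 Hz drive and `P30` the
30 Hz component under 30 Hz drive, and a control ensemble of seeded subjects
providing means and the standard deviation of `P30`:

* `M1 = 1 - P40_PV / mean(P40_Ctrl)` — raw 40 Hz reduction (may be
  negative);
* `M2 = M1` if `|P30_PV - mean(P30_Ctrl)| <= 3 sd(P30_Ctrl)`, else 0 —
  reduction gated by an intact 30 Hz response: vectors whose 30 Hz response
  deviates from the control band are excluded. The 3-sigma boundary counts
  as valid, fixing the measure-zero case deterministically.
* `M3 = (1/2)(1 - P40_PV/mean P40) - (1/2)(1 - P20_PV/mean P20)` for valid
  vectors, else 0 — additionally rewards 20 Hz facilitation.

All metrics are invariant to a global rescaling of powers. Top-5% regions
take the `ceiling(0.05 N)` highest scores over **all** 2025 vectors (invalid
vectors self-exclude under M2/M3 by scoring 0); ties break by enumeration
(lexicographic) order. An among-valid-only variant is available by
subsetting.

## The abnormality grid

Six knobs applied to a baseline network: I->E and I->I decay times (6, 15,
25 ms), connection-count fractions (100, 75, 50%), and weight multipliers
(150, 125, 100, 75, 50%); 3·3·5·5·3·3 = 2025 combinations, enumerated
lexicographically in the column order (n_ie, n_ii, w_ie, w_ii, tau_ie,
tau_ii). Connection pruning permutes each pathway's edge list once under a
dedicated sub-seed and keeps a prefix, so pruned sets are nested across
levels (the 50% network is a subnetwork of the 75% network), reducing
variance between nominally adjacent conditions. Each vector runs once per
drive frequency against a shared baseline seed; ensembles are reserved for
controls and selected vectors. The sweep is checkpointed per vector and
resume-safe.

## Information-theoretic analysis

Entropies are standard `H = -sum p log2 p` in bits. MI of a
parameter subset with the phenotype treats the subset as one compound
variable; nMI = 100·MI/H(Y). Plug-in (maximum-likelihood) estimation without
bias correction is exact here, not an approximation: the sweep enumerates
the entire parameter population, so the empirical joint *is* the joint.

The phenotype discretization of the metric scores is a free design choice;
the default is the binary top-5% rule (aligning the nMI analysis with the region analyses),
with threshold and equal-width k-bin rules exposed. Because nMI values
depend strongly on that discretization, absolute nMI levels are not
comparable across choices; the analysis is validated structurally instead —
against brute-force oracles, and on surrogates with known generative
structure (a single-factor rule concentrates nMI on the causal parameter; an
XOR rule yields zero single-parameter nMI and 100% for the pair).

**XOR surrogates use 2-level sub-grids** on the XOR'd parameters (baseline
vs. one extreme instance). On the full grid a 3-level parameter cannot be
binarized into equal halves (any split is 1/3 vs 2/3), which would leak
~7% nMI into each single parameter and blur the single-vs-pair contrast the
surrogate exists to demonstrate.

## Group statistics

The group comparison is a classical sums-of-squares split-plot ANOVA
(between: GROUP; within: POWER with three levels) with Greenhouse–Geisser
epsilon computed from the pooled within-group covariance of the repeated
measures; corrected dfs are `eps (k-1)` and `eps (k-1)(N-2)`. For `k = 3`,
epsilon is bounded in [0.5, 1]. The implementation is validated against an
independent reference implementation (`car::Anova`, with sum-to-zero
contrasts) to 1e-6 on fixtures. F statistics from any particular simulation
are simulation-dependent quantities, so agreement on fixtures, not specific
F values, is the correctness standard. Powers enter untransformed by default; a log transform
with offset is provided as a variance-stabilization option.

## Problem sizes and surrogates

Desk-scale defaults: tests use a 6x6/3x3 "micro" network with 1.1–1.5 s
runs; the entrainment and decay-time analyses use a 12x12/6x6 "mini" network
with 3 s runs (500 ms transient), 3-subject control ensembles, and 5 seeds
for the prolonged-decay condition. The full 24x24/12x12 network with 10 s
runs and the complete 2025-vector sweep are supported by the same code paths
but are long-running; the analysis scripts state the scale they use. The
surrogate module generates band-power tables over any grid from explicit
generative rules (baseline triple, per-instance multipliers, interaction and
XOR terms, Gaussian noise as a fraction of baseline, an i.i.d. 20-subject
control ensemble) so that the entire metric + nMI + statistics pipeline is
exercised end-to-end in seconds with known ground truth. Surrogates emulate
the *statistical* structure of sweep output (band-power table + control
ensemble); they do not emulate spike correlations or spectral shapes, so
surrogate-based tests validate the analysis pipeline, not the network model.

## Numerical and degenerate-input policy

Rate-function singularities use series limits; gating tables span -130 to
70 mV at 0.05 mV with linear interpolation. Equal rise and decay times fall
back to the alpha function (exact in the exported conductance function; the
simulator perturbs tau2 by 1e-4 relative, well under other model error).
A time step above 0.05 ms is refused unless forced. Zero drive with zero
background yields exactly zero spikes and an identically zero EEG. Windows
shorter than 1 s are refused for spectra (they cannot separate 30 from
40 Hz); halfwidths below the spectral resolution, poisson-mode locking,
single-subject control ensembles, degenerate (all-equal) scores under the
quantile rule, and zero-entropy phenotypes are all explicit errors rather
than silent results.

## Known limitations

* The reduced cells reproduce firing phenotypes, not the cited channel
  kinetics; absolute EEG power is in arbitrary units and only ratios and
  peak locations are meaningful.
* The mini-scale inhibitory population is small (36 cells), so inhibition
  arrives in coarser quanta than at full scale; effect sizes of the
  decay-time manipulations differ from the full-size network even though
  their signs and mechanism agree.
* The thalamic EPSC contribution to the EEG rises when excitatory firing is
  suppressed (recovered driving force), partially offsetting the loss of
  recurrent EPSCs; the calibrated attenuation keeps the recurrent component
  dominant, but the 40 Hz reduction under prolonged I->E decay is
  therefore smaller in relative terms than a full multicompartment
  implementation would show.
* No NMDA receptors, interneuron subtypes, gap junctions, or shunting
  inhibition; evoked (not induced) oscillations only; 20 Hz drive is not
  analyzed.
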