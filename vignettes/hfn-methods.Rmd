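---
title: "Hyper-frequency networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyper-frequency networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science implemented by `hfnet`: what each stage
computes, which parameters matter and why their defaults are what they are,
what the synthetic generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

## The hyper-frequency network idea

Oscillatory multichannel recordings (EEG-like: tens of channels, a few
hundred Hz) synchronize both *within* a frequency (two sites oscillating at
10 Hz with a stable phase relation, WFC) and *across* frequencies (n:m
locking, e.g. a 2 Hz rhythm phase-locked to a 4 Hz rhythm, CFC). A
hyper-frequency network treats every combination of recording site and
frequency of interest as a separate node, so one directed weighted graph
holds both kinds of coupling at once — including cross-frequency coupling
*within* a single site, which pairwise channel networks cannot represent.
With 58 channels and 10 frequencies of interest (2–20 Hz in 2-Hz steps) the
graph has 580 nodes, ordered frequency-major so WFC blocks lie on the block
diagonal of the adjacency.

## Instantaneous phase

Phase is extracted with an analytic Morlet (Gabor) wavelet,

$$w(t, f) = (\sigma^2 \pi)^{-1/4}\, e^{-t^2 / 2\sigma^2}\, e^{2\pi i f t},$$

convolved with each channel and evaluated every `time_step = 5` samples
(20 ms at 250 Hz), giving 500 phase samples on a 10-s segment. The phase is
the complex argument, wrapped to $(-\pi, \pi]$.

Choices here:

* **Envelope width.** The width $\sigma$ per frequency is a free parameter;
  `hfnet` uses a constant-cycles rule $\sigma = n_\mathrm{cycles} / (2\pi f)$
  with `n_cycles = 5` by default (a conventional compromise between temporal
  and spectral resolution), plus a fixed-$\sigma$ mode. Results that depend
  on $\sigma$ should be treated as tunable, not as reproducible constants.
* **Edges.** Convolution uses zero padding; grid points whose $\pm 4\sigma$
  support crosses the segment boundary are flagged in a validity mask.
  Windows that touch invalid points are *flagged but kept* by default
  (`$window_valid`). Excluding them, as one might prefer for strict
  inference, would destroy the fixed geometry of the analysis — at 2 Hz the
  support is ±1.6 s, and a 10-s segment would lose ~30 of its 81 windows —
  so exclusion is left to the user.

## Phase-coupling indices

For channels/frequencies $(X, f_m)$ and $(Y, f_n)$ with $n f_m = m f_n$, the
generalized phase difference is
$\Delta\Phi(t) = n\,\Phi_X(f_m, t) - m\,\Phi_Y(f_n, t)$, wrapped. Within
frequency, $n = m = 1$.

* **PSI** is the modulus of the time-averaged unit phasor
  $|\langle e^{i\Delta\Phi}\rangle|$: 1 for any stable phase relation
  (including anti-phase), ~0 for dispersed phases.
* **Ternary coding** marks each 20-ms point `+1` if
  $\Delta\Phi \in (0, \pi/4)$ (source leads), `-1` if
  $\Delta\Phi \in (-\pi/4, 0)$, else `0`. All three intervals are open:
  exact 0 and $\pm\pi/4$ code 0.
* **Cleaning** zeroes every maximal nonzero run strictly shorter than one
  oscillation period ($T = 1/f$; for CFC pairs the *longer* of the two
  periods by default, configurable to min/mean), removing accidental
  lock-ins. Cleaning runs on the full segment before windowing.
* **PCI / NCI / ACI** are the fractions of window points coded `+1`, `-1`,
  and either; `ACI = PCI + NCI` exactly.
* **ICI**, the directed index the networks are built from, is

  $$\mathrm{ICI} = \frac{\mathrm{PCI} + \mathrm{ACI}}{2\,\mathrm{ACI}}
    \cdot \mathrm{PCI}, \qquad \mathrm{ICI} = 0 \text{ when } \mathrm{ACI} = 0.$$

  This algebraic form was chosen because it reproduces both published limit
  behaviors: all points positive ⇒ prefactor 1, ICI = PCI = 1; all points
  negative ⇒ prefactor 1/2 but PCI = 0, so ICI → 0. Note that under this
  reading ICI does *not* equal 0.5 when positive and negative locked points
  are balanced (it gives $0.75 \cdot \mathrm{PCI}$); the remark suggesting
  0.5 is inconsistent with the limit behaviors and was not silently
  reconciled. The `ACI = 0 ⇒ ICI = 0` convention continues the all-negative
  limit and avoids 0/0.

Windowing uses 2000-ms windows advanced by 100 ms: 81 windows per 10-s
segment. Direction antisymmetry ($\mathrm{PCI}_{ij} = \mathrm{NCI}_{ji}$,
ACI and PSI symmetric) lets `sliding_window_coupling()` compute each
unordered pair once and emit both directed ICIs.

## Network construction and thresholding

The window-w HFN has adjacency $A_{ij} = \mathrm{ICI}_{i \to j}$, zero
diagonal (self-pairs excluded; same-electrode cross-frequency pairs
included). Entries at or below the connectivity threshold (default 0.26) are
zeroed; surviving entries keep their weights — all downstream metrics are
weighted, so the graph is sparsified, not binarized. Cost is the fraction of
possible directed edges present.

The threshold is validated against surrogates: `time-shuffle` permutes
samples, `phase-shuffle` keeps each channel's amplitude spectrum exactly and
randomizes the phase spectrum (permuting the original phase values and
restoring conjugate symmetry). Windowed ICI values from several surrogate
recordings are pooled and the mean is bootstrapped (1000 resamples); the
critical value is the $1-\alpha$ percentile of the bootstrap-mean
distribution ("mean plus one-sided percentile CI"), which reduces to the
mean at $\alpha = 0.5$. ICI rather than PSI enters the bootstrap because the
networks are ICI-based. Percentile (not normal) CIs are used; both the
surrogate scheme and $\alpha$ are configurable.

## Graph metrics

All metrics are nodal, weighted, and directed:

* **Strengths**: $s^{in}_i = \sum_j w_{ji}$, $s^{out}_i = \sum_j w_{ij}$.
* **Clustering** (Fagiolo): cube-root weight products over both triangle
  orientations, $t_i = \tfrac12 [(\hat W + \hat W^T)^3]_{ii}$ with
  $\hat W = W^{1/3}$, normalized by
  $(k^{in}+k^{out})(k^{in}+k^{out}-1) - 2\sum_j a_{ij}a_{ji}$; degree-0/1
  nodes get 0.
* **Distances** use edge length $1/w$ (the Brain-Connectivity-Toolbox
  convention; $1 - w$ is available). Per-node path length averages over
  *reachable* targets only, with the unreachable-pair count reported;
  efficiency gives unreachable pairs $1/\infty = 0$, which is why it is the
  better-behaved measure on disconnected graphs.
* **Local efficiency** (Rubinov–Sporns form): over the out-neighborhood
  $N_i$, $\sum_{j \ne h} (w_{ij} w_{ih} / d_{jh}(N_i))^{1/3} / (k_i(k_i-1))$
  with $d_{jh}$ computed inside the neighborhood subgraph.

**Reference graphs.** The random reference repositions the edges (with
weights) uniformly over off-diagonal slots — deliberately *not*
degree-preserving, matching the literal "randomize the edges" recipe;
Maslov–Sneppen rewiring is available as an option. The lattice reference
starts from such a random permutation and then sorts each column's above-
and below-diagonal parts so the largest weights hug the diagonal, giving a
ring-like topology with the exact same node count, edge count, and weight
multiset. Ties break by a stable sort for determinism. Ten realizations are
averaged by default.

**Small-world coefficients.** $\gamma = CC/CC_{rand}$,
$\lambda = CPL/CPL_{rand}$, $\sigma = \gamma/\lambda$ (> 1 for small-world
graphs); $\omega = CPL_{rand}/CPL - CC/CC_{latt}$ (≈ 0 small-world, > 0
random-leaning, < 0 lattice-leaning); and the efficiency variants
$\sigma_E, \omega_E$. Graph-level means (not node-level) enter these ratios.
A caution from our own calibration: a mildly rewired ring (rewiring
probability 0.1) is still lattice-leaning — it shows $\sigma$ clearly above
1 while $\omega$ sits slightly *below* zero; $\omega$ only crosses zero at
substantially higher rewiring. The two coefficients answer different
questions and should be read together.

## Network topology dynamics

Each nodal metric over the 81 windows forms a nodes × windows matrix.
Pearson correlations between its columns give the temporal (windows ×
windows) similarity; between its rows, the nodal (nodes × nodes) similarity.
Zero-variance rows/columns are excluded with a warning rather than erroring.
Variability summaries use population SDs; the grand mean is identical
whichever axis is averaged first.

Modularity $Q = \tfrac1{l}\sum_{ij}(w_{ij} - k_i k_j / l)\,
\delta_{m_i m_j}$ is optimized by an in-package Louvain implementation
(greedy local moves + aggregation on the modularity matrix, 10 restarts,
fixed seed, best-Q result kept). The temporal matrix is clipped at zero
(negative correlations logged) and partitioned with plain weighted
modularity; the nodal matrix keeps its signs and uses the asymmetric signed
variant $Q^* = Q^+ - \tfrac{v^-}{v^+ + v^-} Q^-$, in which positive weights
reward and negative weights penalize co-assignment. $Q$ for the returned
assignment is always evaluated exactly from its definition (and is exactly 0
for a single module). "State duration" is reported both as windows-per-module
(the definition used in the summary statistics) and as contiguous runs,
since dynamic states are usually but not necessarily contiguous. The null
model shuffles the off-diagonal similarity values (preserving symmetry,
diagonal, and the value multiset) and re-partitions, yielding an empirical
p-value for the observed $Q$.

## Stimulus-related dynamics and the classifier

The segment is divided into inter-stimulus intervals (ISIs) by the stimulus
onsets; each sliding window is labeled with the ISI containing its *onset*
(a window starting exactly at a stimulus joins the new ISI). The features
for one frequency are the windows × channels block of a metric matrix
(81 × 58 at full geometry). The classifier is a three-layer tanh network
(inputs → 8 hidden → one output per class) trained by full-batch
back-propagation on squared error with ±1 one-hot targets; prediction is the
arg-max output. Unstated hyperparameters are configuration, not science:
learning rate 0.1 with momentum 0.9, up to 800 epochs with early stopping
(patience 100), features z-scored per node on the training split only.
Each of 100 repetitions draws an unstratified random 61/20 split of the 81
windows (splits missing a class are redrawn and logged) and reports percent
correct on the held-out windows.

Two systematic effects of this published design are worth knowing:

1. Because consecutive windows overlap by 95%, *any* temporally smooth
   feature variation — signal or noise — encodes time, and ISI class is a
   function of time; a sufficiently flexible classifier can therefore score
   far above nominal chance on features that carry no stimulus-locked
   signal at all. Only feature matrices that are (near-)constant under the
   null avoid this leak.
2. Conversely, on *exactly* constant features the squared-error network
   converges to the training-split class priors and predicts the train-modal
   class; under splits drawn without replacement that class is depleted in
   the test windows, biasing accuracy systematically *below* the nominal
   $1/K$. Chance should therefore be calibrated by permutation, not assumed
   to be $100/K$ exactly.

## The synthetic world

The generator exists so that every stage is testable without external data.
Defaults mirror the method's stated operating point: 250 Hz, 10-s segments,
oddball schedules with ISIs uniform on 1.2–1.5 s and 80/20
standard/deviant classes; the full 58-channel geometry is configurable but
unit tests use 4–13 channels.

`gen_coupled_oscillators()` builds channels as sums of (optionally
phase-diffusing) sinusoids plus white Gaussian noise at a per-oscillator
SNR; `coupled_to` slaves an oscillator's phase so that
$n\Phi_A - m\Phi_B = \mathrm{lag}$ up to smoothed wrapped jitter — coupling
is planted *by construction*, which is what makes closed-form expectations
(PSI = 1, ICI = 1, constant generalized phase differences) exact.

`gen_event_modulated_recording()` plants stimulus-related dynamics: channels
are assigned round-robin to ISI classes and phase-lock to a reference
channel (lag centered on $+\pi/8$, the middle of the positive coding range)
only while their class is active. The *uncoupled* state is a deterministic
frequency detuning (signed multiples of 0.45 Hz): every pairwise phase
difference then sweeps the circle at a fixed rate, so its in-phase duty
cycle per 2-s window is a constant safely below the 0.26 threshold. This is
deliberate — with a stochastic (random-walk) null, occasional long chance
lock-ins exceed the threshold and drift smoothly across the overlapping
windows, re-creating leak (1) above; the detuned null is the configuration
in which "no effect" genuinely means "no decodable structure".
`effect_size` scales the suppression of drift and jitter plus an exponential
pull of the wrapped lag error toward zero (rate 40/s at effect 1), so 0
leaves all channels free-running and 1 gives rigid in-ISI locking.

What the generator does **not** emulate: 1/f background spectra, volume
conduction/field spread, amplitude dynamics, non-sinusoidal waveforms, or
artifacts. A green end-to-end test therefore establishes that the *method
pipeline* recovers planted phase structure — not that any of these
real-data complications are handled.

## Numerical conventions

* Phases wrap to $(-\pi, \pi]$; zero-magnitude wavelet coefficients emit
  phase 0 and are flagged.
* Cleaning compares run duration *strictly* against the period ("shorter
  than" is strict).
* Thresholding zeroes entries $\le$ threshold and is idempotent; cost is
  monotone non-increasing in the threshold.
* Reference-graph and Louvain randomness, splits, and weight
  initializations all derive from explicit seeds; identical seeds give
  byte-identical outputs.
* The pipeline writes every stage's artifact (coupling tables, dynamics
  matrices, similarity matrices, partitions, summaries, a seed/config
  manifest) to the output directory, but orchestration is in-memory; stages
  are re-run, not resumed, on repeated invocations.
* Recordings interchange as delimited text (samples × channels, header of
  labels) with a JSON sidecar for the sampling rate and a two-column TSV
  for schedules. EDF is not supported: no EDF library is available in the
  target environment and a hand-rolled binary writer would be worse than
  none.

## Known limitations

* $\sigma$ (cycle count) of the wavelet, the classifier's hyperparameters,
  and the surrogate CI construction are conventions, not reproducible
  constants; all are exposed in configuration.
* Coupling analysis at full 580-node geometry is $O(N^2)$ pairs × windows;
  pure-R vectorization handles the 58-channel single-frequency case in
  seconds, but all-10-FOI full-pair runs are minutes-scale.
* The classifier measures *association between features and ISI labels
  under split resampling*; see the two systematic effects above before
  interpreting accuracies near either chance or 100%.
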