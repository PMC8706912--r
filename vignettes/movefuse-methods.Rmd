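---
title: "Fusion classification of multi-axial movement signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion classification of multi-axial movement signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movefuse)
```

## The classification problem

A segmented movement is the bundle of `M_G = Σ m_g` uniaxial time series
recorded by `G` multi-axial sensors (in the motivating setting: a 3-axis
accelerometer and a 3-axis gyroscope at ±16 g / ±2000 dps, 100 Hz, on the
striking limb). Movements belong to one of `H` classes. Trial-to-trial
variation within a class is *non-linear*: peaks shift in latency and signal
segments expand or compress, on top of additive noise and unequal raw
durations. The package classifies such movements *feature-blind* — raw
channels go straight into the classifiers, no hand-engineered features.

## Input models

The four input models differ only in where the channels are fused:

* **VI** keeps the `M_G` channels separate (fusion happens at the output);
  the most flexible model — heterogeneous sensors, unequal durations,
  unsynchronized warps are all fine — but it needs `M_G` classifiers.
* **LMI** stacks each sensor's axes into a matrix `Z_g (m_g × n_g)`;
  assumes equal durations and synchronized warps *within* each sensor.
* **GMI** stacks everything into a global matrix `Z (M_G × N)`; additionally
  assumes synchronization *across* sensors.
* **GCI** stacks the per-sensor matrices into a cuboid `Z (M × N × G)`;
  requires all sensors to share the same axis count `M`, and is rejected
  with a clear error otherwise.

Equal durations are produced by linear expansion/compression
(`duration_normalize()`): the common length is the rounded mean duration —
global for GMI/GCI, per sensor for LMI (`fit_normalization()`). Rounding is
half-away-from-zero so the targets are deterministic. Row order in the
global matrix is sensor-major then axis, and cuboid depth follows the
sensor index; the order is arbitrary but must be identical at train and
test time, so it is fixed once here. Intervals are half-open and 0-based
internally; user-facing tables are 1-based.

Amplitude normalization (min-max per axis, pooled over the whole training
set) is available for heterogeneous sensors but **off by default**: pooling
per axis preserves between-class amplitude information that per-trial
scaling would destroy, and homogeneous-IMU data does not need the map. Test
values outside the training range are deliberately not clipped — the map is
affine, not a squashing function. A constant training axis raises an error
naming the axis rather than silently producing NaNs.

`segment_energy()` is a deliberately minimal energy detector (rectangular
sliding window over the summed squared channels, threshold relative to the
global peak, gap merging) for carving strikes out of a continuous stream.
The classifiers consume pre-segmented movements; nothing downstream depends
on its exact boundaries.

## Dynamic time warping

The discrepancy between two signals is the path-length-normalized cost of
the optimal warping path,

`A_XY = min_W (1/K) Σ_k d[w(k)]`,

over paths satisfying the endpoint, monotonicity and continuity
constraints, with the classic symmetric step set {(1,0), (0,1), (1,1)} and
unit weights. Local costs are Euclidean (default), Manhattan or squared
Euclidean between scalars, matrix columns, or cuboid depth-frames. Cuboid
alignment is implemented by stacking the frames into an `(M·G × N)` matrix,
which provably yields the same per-step costs — a property the test suite
checks numerically to 1e-9. For the same reason no separate cuboid DTW
classifier exists: it would be identical to the global-matrix one.

**Objective.** The textbook recursion minimizes the *unnormalized* sum and
divides by the realized path length afterwards; that composite does not
always minimize the normalized cost itself (for `X = [0,4]`, `Y = [0,0]`
the min-sum path has `K = 2` and normalized cost 2, while a `K = 3` path
averages to 4/3). Since the discrepancy is *defined* as the minimum of the
normalized cost, `dtw_align()` minimizes it exactly with a dynamic program
stratified by path length (`O(n·m·(n+m))` in compiled code); the classic
min-sum recursion stays available as `objective = "sum"`. An exhaustive
enumeration oracle (`brute_force_align()`, capped at length 6) pins the
implementation down in the tests. Ties on the normalized value prefer the
shorter path, then diagonal-first backtracking, so the reported path is
deterministic. No global band constraint is applied — full DP table.

**Classifiers.** One reference template per class is estimated by
element-wise central tendency over the class's training set
(`fit_templates()`); the sample mean is the default, with median, trimmed
mean, winsorized mean and trimean exposed because a better location
estimate does not necessarily classify better — no ordering is asserted or
assumed. Averaging needs equal lengths, so templates are estimated after
duration normalization; for the VI model each channel is normalized to its
own training-mean length (the channel itself is aligned at test time at its
raw length — DTW does not care). DTW-1 averages the `M_G` per-channel
discrepancies, DTW-2 the `G` per-sensor matrix discrepancies, DTW-3 aligns
the global matrix directly; all three decide by `argmin`, ties to the
lowest class index.

## Convolutional networks

All four CNN models share the fixed architecture
conv–conv–pool–FC(sigmoid)–FC(softmax) with `K = 32 + 32` filters, "same"
convolutions (stride 1, zero padding `(f−1)/2`), max pooling and a softmax
output of width `H`; the first-layer filter geometry follows the input
model: `1×3×1` (CNN-1), `3×3×1` (CNN-2, CNN-3), `3×3×G` (CNN-4 — convolving
two equal-depth cuboids yields a matrix). The layers compute correlation,
not flipped convolution, which is the universal deep-learning convention.
The dimension chain `H' = 1 + (H − f + 2p)/s` (floor division when not
exact) is asserted programmatically for every architecture the package
builds.

Choices the architecture description leaves open were fixed once as
conventional defaults, all configurable: pooling `1×2` for vector inputs
and `2×2` otherwise, stride 2, windows clipped to the available extent;
hidden FC width 100; Adam with learning rate 1e-3, batch 32, up to 200
epochs with early stopping (patience 10) on a 10% stratified validation
split, plus a training-loss floor of 1e-4 that ends training early on
trivially separable data. Per-net seeds derive from the master seed plus
the net index and are recorded in the training log; fixed seed and thread
count reproduce the loss trajectory bit for bit.

CNN-1 trains one net per channel (`M_G` nets) and CNN-2 one per sensor
(`G` nets); their posterior vectors are fused by element-wise averaging,
which preserves the sum-to-one property, before the maximum-response
`argmax` decision (ties to the lowest index). CNN-3/4 are single nets and
need no output fusion.

## The synthetic movement simulator

Real strike ensembles show blurred, misaligned peaks across trials of one
class. The generator reproduces exactly that phenomenology: per-class,
per-channel templates are sums of Gaussian bumps (3 by default, widths
4–10% of the duration, signed amplitudes 0.6–1.5); each trial composes its
template with a random strictly increasing piecewise-linear time map
(8 knots, local slopes within `1 ± λ_w`), shifts it by an integer latency
drawn from `±τ` with edge replication, adds Gaussian noise, and draws its
raw duration from `N0 ± jitter`. A `separation` control blends
class-specific against channel-common template components, so class
difficulty is tunable. Because the input models differ precisely in which
warp synchronization they assume, warp sharing is an explicit toggle:
per sensor (default — the LMI assumption), global (the GMI assumption), or
per channel (the VI-only regime). All randomness flows from one master
seed through pre-drawn per-trial seeds, so ensembles are reproducible
record for record.

What the simulator does *not* emulate: limb kinematics, gravity and
orientation artifacts, sensor-specific spectra, inter-subject structure.
Passing tests on synthetic ensembles therefore demonstrate correctness of
the fusion and alignment machinery under the stated variation model, not
field performance on any particular sport dataset.

The **benchmark configuration** (`benchmark_config()`) fixes the study
conditions for the fusion-versus-uniaxial comparison: `H = 8` classes, 2
sensors × 3 axes, 12 trials/class, `N0 = 80` with ±5 jitter,
`λ_w = 0.25`, `τ = 10`, per-sensor warp sharing, separation 0.6, and noise
`σ = 0.6`. The noise level was calibrated once so that single-axis
classifiers land in the 50–80% band — hard enough that fusion has headroom,
easy enough that channels are informative — and then frozen.

## Evaluation protocol

`repeated_holdout()` draws stratified 80/20 train/test splits, refits the
full pipeline (normalization spec, templates or nets) on each training
fold, scores the test fold, and averages accuracies over repetitions
(100 in the full protocol; smaller values trade estimator precision for
runtime — reports carry the repetition count). Stratification is a
deliberate choice: plain random splits can drop a class from a small
training fold entirely. Reports carry per-repetition accuracies, a summed
confusion matrix, the seeds, and a digest of the evaluated ensemble;
`fusion_vs_uniaxial_summary()` refuses to compare reports from different
ensembles. `random_baseline(H) = 100/H`% is the reference chance level
(5.6% at `H = 18`).

The test suite exercises, at desk scale: exactness of the dynamic program
against path enumeration (500 random pairs, lengths ≤ 5), the
cuboid/matrix equivalence (100 random cuboid pairs, 1e-9), the dimension
algebra of all four architectures (50 random input sizes), the
zero-corruption limit in which all seven classifiers must score 100%
(`H = 6`, 20 trials/class, 5 repetitions), the benchmark
fusion-beats-uniaxial comparison at 10 repetitions, chance-level
calibration under permuted labels (`H = 18`, within 3 binomial standard
errors), and bitwise reproducibility of reports and training trajectories.
CNN runs in these checks use 25–40 epochs without (clean limit) or with
the validation split; those counts are the package's desk-scale defaults
for the simulated ensembles, chosen to converge comfortably at these
problem sizes.

## Known limitations

* Exact normalized-cost DTW costs a factor `n+m` over the classic
  recursion; for very long signals (`n` in the thousands) `objective =
  "sum"` is the pragmatic choice.
* Plain element-wise template averaging blurs under strong within-class
  warps; warp-aware barycenters are out of scope.
* The CNN engine is deliberately minimal (fixed layer stack, no
  augmentation, no schedulers); it implements the four fusion models, not a
  general deep-learning framework.
* `segment_energy()` is a stand-in detector, not a validated onset
  algorithm.
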