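---
title: "Corner and endpoint detection with a spiking HT3D network: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corner and endpoint detection with a spiking HT3D network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ht3dsnn)
```

## The model

HT3D extends the classical Hough transform for lines with a third parameter.
A cell $(\theta, d, p)$ of the parameter space stands for the *segment* of
the line $d = x\cos\theta + y\sin\theta$ that runs from the lowest
representable position up to $p$, where
$p = -x\sin\theta + y\cos\theta$ is the position of a point along the line.
With the image origin at its center, $\theta \in [0, \pi)$ and
$d, p \in [-R, R]$, $R$ being half the image diagonal. Voting happens in two
stages: every edge pixel votes once per orientation for the cell of its own
$(d, p)$, and an in-column prefix sum along $p$ then turns these first-stage
votes into the complete scheme in which a cell counts all points at or below
its position. Consequently the difference of two cells of a column counts
the edge points lying between their positions, and segment *ends* become
local cell patterns: a *full* run of $\eta$ cells (difference above
$\tau_F$) with an *empty* cell beyond it (difference below $\tau_E$),
flanked by two lateral columns whose content distinguishes a non-intersection
endpoint (both laterals quiet) from a corner (a second full run appears in
another orientation plane at an angular offset within the corner range).
Both pattern families exist in a flipped version, covering segments that end
downward rather than upward in $p$.

The package implements this algorithm twice:

* `ht3d_transform()` / `detect_patterns()` / `ht3d_detect()` — the plain
  array implementation, used both as a standalone detector and as the oracle
  for the network;
* `ht3d_snn_build()` / `ht3d_snn_detect()` — the same computation expressed
  as a network of leaky integrate-and-fire (LIF) neurons with weighted,
  integer-delayed synapses, simulated event-drivenly and deterministically.

A LIF neuron here leaks linearly and only updates on input: on an arrival at
tick $t$, $P' = \mathrm{sign}(P)\,\max(|P| - \lambda \Delta t, 0)$, then the
summed same-tick input is added and the neuron fires and resets to zero when
$P \ge \Theta$. There is no refractory period and no randomness. The pure-R
`lif_trajectory()` implements exactly this rule and serves as the
independent cross-check of the compiled engine.

## How spikes encode votes

Each orientation layer holds one relay neuron per $d$-column and 1-pixel
$p$-row. Edge pixels inject one spike per layer into the cell of their own
$(d, p)$; a feedforward synapse from each row to the next (weight 1, delay
1 tick) propagates every spike up the column, so that over a settled run the
spike count of a Hough neuron equals its accumulated vote count. Difference
(subpattern) neurons receive paired inputs from two cells of a column — an
excitatory synapse from the upper cell and an inhibitory one of equal
magnitude from the cell $l$ rows below, delayed by $l$ extra ticks. Because
propagation runs at exactly one row per tick, the two spike trains arrive in
lockstep and common votes cancel to the tick; the neuron's output spike
count is exactly the vote difference over the piece of segment. Three
difference lengths are wired: $\Delta p$ (u), $(\eta-1)\Delta p$ (s) and
$\eta\Delta p$ (c).

One detail is forced by the exactness contract. Two distinct pixels can
quantize into the *same* cell; injected at the same tick their spikes would
merge under the summation rule and a vote would vanish from every count
downstream. `inject_edges()` therefore injects same-cell duplicates as a
short burst on successive ticks and chooses burst offsets so that within a
column no two votes ever share a propagation phase (for a vote at row $r$
with offset $k$, the value $k - r$ is kept unique per column). With that,
spike counts equal the array transform *exactly* on every input, which the
test-suite asserts over randomized scenes and the `compare` command checks
on demand.

## Pattern, combination and readout stages

Endpoint (p1) neurons follow the pattern wiring: strong vetoes
($w_{uI} = -\eta\Delta p\, w_{cE}$) from the three u-neurons of the cell
beyond the run in all three columns, excitation $w_{cE}$ from the central
c-neuron, and weak penalties ($w_{cI} = -\rho_{p1} w_{cE}$) from the lateral
c-neurons. Corner half-pattern (p2) neurons take central c excitation and
lateral s penalties ($w_{sI} = -\rho_{p2} w_{cE}$). With $w_{cE} = 1$ the
firing thresholds are $\Theta_{p1} = \eta\Delta p - \xi_{p1}$ and
$\Theta_{p2} = \eta\Delta p - \xi_{p2}$, where the slack $\xi$ absorbs the
leak accumulated over the spike train, tolerated gaps in the segment, and
allowed lateral penalties. Defaults are the reference set:
$\lambda = 0.2$/tick, $\rho_{p1} = \rho_{p2} = 0.25$, $\Theta_{p1} = 6.5$,
$\Theta_{p2} = 8$, $\eta = 6$, $\Delta d = \Delta p = 2$,
$\Delta\theta = 0.04$ (half the resolution bound
$\arctan(1/(\eta\Delta p))$, so every feature is seen by more than one
layer), corner range 35–145°.

At the level of the original algorithm, corner confirmation is a product: a corner
exists where a local half-pattern coincides with a half-pattern at an
angular offset inside the corner range. The spiking realization used here is
coincidence detection. A pooling unit per cell (threshold $w_{cE}$) receives
the p2 outputs, of either version, of every layer at an in-range offset, at
the cell that maps to the same image position (an exact rotation in
$(d, p)$ between layer frames); a strong inhibitory self-synapse makes it
report pooled support about once per run rather than once per remote spike.
The product unit has the two inputs of the original formulation — local p2
and its pooling unit — with threshold 1.8, between one and two unit inputs,
and a leak of $(2 - 1.8)/(\eta\Delta p)$ per tick so the coincidence window
is $\eta\Delta p$ ticks. A first draft let pooled remote support alone cross
the threshold; straight segments then confirmed spurious corners through
pairs of near-parallel layers, which is why the local input is required —
that is also exactly the product semantics.

Detector cells project back to an image-registered endpoint sheet: each
pixel receives synapses from the four detector units (p1 and product, both
versions) of its own discrete Hough cell per layer. Sheet neurons are pure
integrators (infinite threshold, zero leak by default), so their final
potential is the accumulated detector evidence. Surround inhibition is
resolved at readout as greedy winner-take-all: winners in descending
potential, each suppressing a $w \times w$ neighborhood
($w = 2\max(\Delta d, \Delta p) + 1$), ties in raster order, accepting only
potentials $\ge \Theta_e = 2$ — i.e. support from at least two detector
cells, which given $\Delta\theta$ at half the bound means more than one
orientation layer. Edge gating restricts winners to edge pixels and is
implemented as the readout mask (behaviorally equivalent to per-neuron
enable inputs, and simpler to reason about). The reported *kind* of a winner
is the pattern family that contributed most evidence; clean right-angle
corners frequently also satisfy the endpoint pattern, so position — not kind
— is what the evaluation matches, as in the ground-truth protocol.

## Numerical choices and degenerate inputs

* Quantization uses round-half-away-from-zero everywhere (platform-stable);
  $\theta$ bins are left-closed with layer $k$ representing angle
  $k\Delta\theta$, so axis-aligned structure falls exactly on layer 0.
  Rounding can land exactly one bin past the last $d$-column; both
  implementations clamp identically so the equivalence contract is
  preserved.
* Patterns whose support would leave the parameter space, and the two border
  $d$-columns, are skipped rather than zero-padded — no spurious border
  features.
* Event ties are processed in (time, presynaptic id) order and same-tick
  inputs are summed before the threshold test; runs are bit-reproducible.
* The simulation horizon is derived from the layout
  (`n_rows` + $\eta\Delta p$ + margin + latest injection tick), after which
  the network is provably quiet.
* Zero-delay self-synapses are rejected (they would loop within a tick).
* Empty edge maps yield empty accumulators, no events and no detections;
  degenerate build geometries ($\eta\Delta p \ge$ the $p$-range) are
  rejected at build time.

## What the generators emulate — and what they do not

`make_segment()`, `make_polygon()`, `make_rectangle()` and `make_L()`
rasterize ideal 1-pixel-wide digital lines with the integer midpoint
algorithm and carry exact ground truth (vertex pixels for corners with their
interior angle, open ends as endpoints). `degrade()` adds seeded gaps and
spurious pixels; `render_intensity()` paints a matching grayscale image for
the localization stage. This emulates the input the detector expects from an
upstream edge detector: binary, thin, geometrically clean. It does *not*
emulate texture, curvature, anti-aliasing, contrast-dependent edge dropout
or the clutter of natural scenes — passing tests on these fixtures
demonstrates correctness of the transform, the network and the readout, not
detector performance on photographs.

Test and example problem sizes are deliberately modest — scenes up to
128×128 at the reference parameter set (a network of ~8.5M neurons and
~87M synapses that builds in seconds and settles in a few million events)
and randomized 32–64 pixel scenes for the equivalence sweeps; they are the
sizes at which every property can be checked exhaustively and quickly.

## Known limitations

* At very coarse pattern geometry (e.g. $\eta = 3$, $\Delta p = 2$) the
  full-piece test tolerates ~22° of orientation error, overlapping the 35°
  corner-range minimum: interior cells of straight segments can then
  cross-confirm as corners in either implementation. The reference
  parameter set ($\eta = 6$, ~7° tolerance) is free of this; corner studies
  should keep $\eta \ge 4$.
* The array detector's default $\tau_F = \eta\Delta p - 2$ is strict: an
  oblique digital line whose best column captures exactly $\tau_F$ votes is
  not "full", so at default thresholds the array detector favors
  column-aligned segments, while the spiking thresholds
  ($\Theta_{p1} = 6.5$) are more tolerant. Both are configurable; the
  equivalence contract between the two implementations is at the level of
  vote counts, not final detections.
* The gap-tolerance slack is exact only without leak: with $\lambda = 0$,
  endpoints survive up to
  $\lfloor \eta\Delta p - \Theta_{p1} \rfloor = 5$ missing pixels in the
  terminal full piece and are lost beyond it; with $\lambda = 0.2$ the leak
  consumes part of the slack and the practical tolerance is ~3 pixels.
* Line-segment and polygon/rectangle detection, learning of weights, and
  hardware backends are out of scope; the architecture exposes the pairs of
  Hough neurons a segment unit would read, but no such units are built.

## Reproducing the worked numbers

```{r example, eval = FALSE}
# membrane trajectory of the five-spike example (fires on the fifth)
lif_trajectory(1:5, 1, threshold = 4, decay = 0.2)

# derived weights at the reference settings
snn_weights(eta = 6, delta_p = 2)           # w_uI = -12, w_cI = -0.25
max_angular_step(6, 2)                      # 0.0831; half of it is used
num_orientation_steps(0.04)                 # 79 layers

# full pipeline on a synthetic scene
sp <- hough_spec(128, 128)
net <- ht3d_snn_build(sp, snn_params())
sc <- standard_scene("L120", c(128, 128))
run <- ht3d_snn_detect(sc, net)
match_points(run$detections, scene_ground_truth(sc))
```

`scripts/acceptance.R` recomputes all of the above plus the equivalence
sweep and fixture hit rates and writes them to JSON.
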