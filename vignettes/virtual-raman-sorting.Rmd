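---
title: "A virtual Raman image-activated cell sorter: models, parameters and design choices"
author: "SRSflowSort"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SRSflowSort)
```

# What the package models

Raman image-activated cell sorting combines three real-time subsystems: a
multicolor stimulated Raman scattering (SRS) line-scan microscope that images
cells in flow, an image-analysis chain that turns each event's image into a
sort/unsort decision, and an on-chip dual-membrane push-pull sorter that
deflects decided cells into side channels. `SRSflowSort` re-creates this
instrument as a virtual one: a synthetic acquisition generator with full
ground truth, the analysis chain, and the sorter — both as an analytic
Poisson coincidence model and as a Monte-Carlo event-stream simulation —
so that the throughput–purity behavior of the design can be studied and the
analysis chain validated quantitatively.

The package deliberately stops at the signal level. Optics (pulse
synchronization, lock-in demodulation, beam shaping), microfluidic
fabrication, acoustic focusing physics and the FPGA/network fabric of the
real instrument are out of scope; their *effects* enter only through a small
set of acquisition parameters.

# The acquisition model

## Geometry and timing

`acquisitionConfig()` fixes the virtual microscope at the instrument's
operating point:

| parameter        | default | unit  | meaning |
|------------------|---------|-------|---------|
| `lineRate`       | 48000   | 1/s   | line-scan rate (21 µs per line) |
| `nLateralPixels` | 24      | —     | detector pixels across the channel |
| `nColors`        | 4       | —     | acquisition wavenumbers per pixel |
| `lateralFOV`     | 24      | µm    | lateral field of view |
| `flowFOV`        | 33      | µm    | nominal flow-direction frame extent |
| `frameLines`     | 122     | —     | lines per event frame |
| `flowSpeed`      | 0.04    | m/s   | particle velocity |
| `noiseSigma`     | 1/30    | a.u.  | additive Gaussian noise SD |
| `fscPulseWidth`  | 0       | s     | minimum forward-scatter pulse width |

Two geometric conventions deserve comment.

First, 122 lines at 48 kHz and 0.04 m/s correspond to about 102 µm of
travel, not the nominal 33 µm frame extent; the two are reconciled in the
real instrument by magnification that this package does not model. The
simulator therefore exposes `flowSpeed` and `frameLines` independently. The
pure geometry function `normalizeSquare()` keeps the nominal convention — a
122 × 24 px frame with a 33 × 24 µm field of view resamples to 122 × 89
square pixels — while the end-to-end pipeline (`processStream()`,
`virtualSortExperiment()`) derives the frame's physical flow extent from
`flowSpeed / lineRate × frameLines` so that pixel areas, and with them the
density features, are internally consistent with the rendered physics.

Second, the four colors are treated as co-registered channels of one line.
The real instrument time-multiplexes wavelengths a few hundred nanoseconds
apart — two orders of magnitude below the line period — and demultiplexes in
hardware, so this abstraction costs nothing at the scales modeled here.

## Specimens and noise

Arrivals are a homogeneous Poisson process (`simulateArrivals()`):
exponential gaps with mean `1/rate`, each event independently a target with
probability `targetFraction`. The defaults mirror the polymer-bead
validation experiment: 5 µm PMMA targets and 6 µm polystyrene (PS)
nontargets mixed 1:1.5 (target fraction 0.6). Specimens are rendered as
disks in (time × lateral) coordinates whose per-pixel signal is
`responses(basis) %*% concentration`; optional droplet texture
(`addDroplets()`) multiplies the concentration inside internal inclusions,
emulating lipid-droplet heterogeneity. Lateral position jitter is a
truncated Gaussian (SD 1 µm, bound ±3 µm), a stand-in for residual
focusing error.

Noise is i.i.d. Gaussian per pixel and color. Shot-noise-limited SRS
detection is approximately Gaussian; the default `noiseSigma = 1/30` gives
a peak signal-to-noise ratio of 30 for unit-amplitude specimens, matching
the imaging-performance figure reported for the real microscope. What the
generator does **not** emulate: optical point-spread blur, lock-in filter
dynamics, cell-shape irregularity beyond disks-with-droplets, chromatic
co-registration error, or correlated noise. Passing tests therefore
demonstrate the correctness of the *computational chain* under controlled
conditions, not robustness to every artifact of real acquisitions.

The forward-scatter (FSC) trace used for triggering is the summed occluded
chord of all specimens at each line time, in µm: a disk of radius *R*
produces a pulse of duration 2*R*/*v* and peak 2*R*. `fscPulseWidth` acts
only as a minimum pulse duration (for sub-line specimens) and defaults to
zero, keeping the pulse purely kinematic.

# Spectral unmixing

Each pixel's measurement **d** (one value per color) is modeled as
**d** = **S c**, with **S** the basis matrix whose column *i* is
constituent *i*'s response at the acquisition wavenumbers and **c** the
concentrations. `unmix()` multiplies by the Moore–Penrose pseudo-inverse of
**S**, i.e. returns the minimum-norm least-squares solution; with a square
invertible basis this is the exact inverse. Design choices:

* **Negative concentrations are retained.** The decomposition is linear and
  unbiased; clipping would bias noise statistics. Clipping at zero is
  available as a display/feature-stage option (`clipNegative` in
  `extractFeatures()`).
* **Basis construction interpolates linearly** between tabulated spectrum
  points (`buildBasis()`); sampling is rejected outside the tabulated range.
* **Rank is checked** at basis construction with a singular-value threshold
  of 1e-10 × the largest singular value — the standard numerical tolerance
  for a well-scaled problem.
* Measured backgrounds (water, medium) are handled by background
  *correction* in the mask pipeline rather than by an explicit background
  constituent; a user can model the latter by adding a column to the
  spectra table.

The default basis samples synthetic two-peak PS/PMMA spectra
(`referenceSpectra()`) at 2899, 2954, 3006 and 3034 cm⁻¹. These spectra are
synthetic stand-ins shaped like the C–H stretch region of the real
polymers, adequate for exercising the algebra but not spectroscopic data.

# The image pipeline

Per event: threshold trigger on the FSC trace (`detectEvents()`, with a
refractory window against re-triggers), extraction of `frameLines`
consecutive lines (`frameEvent()`; frames that run past the stream end are
flagged aborted and excluded from features), square-pixel normalization
(`normalizeSquare()`, linear interpolation along the lateral axis, width
rounded half-up — reproducing 89 from 88.73), spectral decomposition
(`unmixImage()`), masking, feature extraction, and gating.

## Masking

`segment()` follows the classical chain: per-column median background
correction using the first and last 5 frame rows (assumed specimen-free),
Gaussian smoothing (σ = 1 px), white top-hat with a disk of radius 15 px
(larger than any specimen, flattening residual background), Canny edge
detection with hysteresis thresholds (0.1, 0.3) × the filtered-image
maximum, contour closing by dilation → flood-fill → erosion (disk radius
2 px), and finally the convex hull of the largest connected component.
EBImage supplies the morphology; the Canny detector (Sobel gradients,
non-maximum suppression, hysteresis linking via connected components) is
implemented in the package. Numerical conventions:

* **Noise floor.** Because the hysteresis thresholds are relative to the
  image maximum, a blank frame would otherwise always yield "edges". Edges
  are rejected unless the strong threshold exceeds 3 × the background MAD
  of the filtered image, so blank frames give empty masks — a valid outcome
  throughout the pipeline.
* **Half-maximum refinement.** The Canny ridge straddles the true boundary
  by about half a pixel. Before the hull, the component is restricted to
  pixels at or above 0.5 × its robust (95th percentile) peak; for a blurred
  step edge the half-maximum contour coincides with the true boundary. On
  noiseless disk phantoms of radius 3–12 px this keeps the mask area within
  about 12% of πr² (worst at the smallest radius), against a 15% budget.
* **Convexity.** The returned mask is the row-span rasterization of the
  convex hull of its pixel centers (boundary pixels inclusive) and is a
  fixpoint of that operation, so "mask equals its own convex hull" is an
  invariant.
* **One mask per frame.** Multi-object frames yield the largest component
  only; splitting coincident cells is a non-goal.
* **Mask channel.** The constituent image with the largest total frame
  signal, overridable — the instrument's "selected color image" without a
  stated selection rule.

## Features and gating

`extractFeatures()` computes, over mask pixels only: area (px and µm²) and
per-constituent total, mean, maximum and SD, plus the *density* = total
intensity / area (µm⁻²) — the per-area intensities used to separate species.
The within-mask SD is the feature that captures droplet heterogeneity: a
specimen rendered with droplet texture has strictly larger SD in the
textured constituent than the same specimen without. Empty masks produce a
flagged record and are **never** sorted.

`decide()` applies a rectangle or polygon gate in a 2-D feature space with
an *inclusive* boundary — an arbitrary but fixed convention required for
determinism. The default two-species gate (`densityGate()`) sorts events
whose target-constituent density exceeds half the expected pure-specimen
density while the nontarget density stays below half of its own.

# The sorter model

## Displacement rules

The dual-membrane push-pull sorter deflects particles with a transverse
flow pulse; successive actuations alternate direction, and both side
channels feed the collection outlet. The quantitative outcome table for
coincident particles is not fully specified by the published description,
so the package reconstructs it from the narrated working principles:

1. every particle *classified* as a target triggers an actuation at its
   sort-point arrival time;
2. actuation directions alternate globally (+1, −1, +1, …);
3. an actuation at time *t* displaces every particle with sort-point
   arrival time *tᵢ* satisfying |*tᵢ* − *t*| < τ by one lateral step in the
   actuation direction, where τ is half the sort window;
4. lateral state saturates at one step: a same-direction push on a
   displaced particle leaves it in place, an opposite push returns it to
   the center; a particle exits to a side channel (collection) iff its
   state is nonzero.

Because directions alternate globally, the actuations affecting any one
particle alternate too, and its exit state reduces to the *parity* of the
number of in-window actuations — the closed form the Monte-Carlo engine
uses. The 32-scenario outcome table derived from these rules is validated
in the tests against an independent literal (sequential-displacement)
implementation, and reproduces the narrated coincidence false positive: a
nontarget preceded within τ by a target is carried into a side channel,
while the following target's opposite push, farther than τ away, cannot
return it.

One scenario family is genuinely ambiguous in the published description: a
*target* preceded by an in-window actuation. Under the rules above the pair
cancels (the particle of interest ends centered — a false negative); a
plausible alternative reading lets the particle's own push dominate (true
positive). Both are implemented behind `variant =` (`"alternating"`,
default, and `"self-priority"`); the default follows mechanically from the
reconstruction that reproduces the narrated scenario, including its
counterfactual.

## Analytic throughput–purity model

For Poisson arrivals at rate λ the probability that a neighbor gap is
shorter than τ is p = 1 − e^(−λτ) (`intervalProb()`). The sort outcome of a
particle is assumed to depend on five binary factors — the target identities
of itself and its two neighbors, and whether each adjacent gap is shorter
than τ — spanning 2⁵ = 32 scenarios (`enumerateScenarios()`), each with
probability the product of its five factor probabilities. Purity is

Purity(λ, τ, r) = ΣP_TP / (ΣP_TP + ΣP_FP),

summing scenario probabilities by outcome (`purityAnalytic()`). τ follows
from the sorting-region transit: τ = sortRegionLength / flowSpeed / 2
(120 µm and 0.04 m/s give the instrument's 3 ms sort window), so faster
flow shortens the coincidence window and raises purity at fixed throughput
— the ordering of the theoretical curve family (`throughputPurityCurve()`).

The nearest-neighbor assumption ignores second neighbors, whose in-window
probability is O(p²). The Monte-Carlo simulator (`simulateSorting()`)
applies the displacement rules over the whole stream, so analytic and
empirical purity are asserted to agree within 3 binomial standard errors
where λτ ≤ 0.1, and within 3 SE + p² beyond; at the instrument's operating
points (λτ ≈ 0.075–0.13) the two agree to a few parts per thousand at 10⁵
events.

## Metrics

`eventRate()` implements the 50-event sliding window, e_i = 50 / (t_i −
t_{i−50}) for i ≥ 51, with the nominal throughput taken as the most
frequent value — the median of the rates in the modal 1-eps histogram bin,
which makes a perfectly regular stream report its exact rate. (With
decimal spacings the rates are exact only up to the binary representation
of the inputs.) `purityYield()` applies the count definitions: purity =
targets collected / all collected, yield = targets collected / all targets;
an empty collection reports purity as undefined (NA), never 0.

# Problem sizes and determinism

The shipped tests validate: unmixing recovery to 1e-9 over random bases
(colors 2–6); Monte-Carlo vs analytic purity at 10⁵ events per grid point
over λ ∈ {1…200} /s, τ ∈ {0.5, 1.5, 3} ms, r ∈ {0.1, 0.6, 0.9}; the full
imaging chain on 10⁴ rendered events at SNR 30 (gate accuracy ≥ 99%
against ground truth); and segmentation on disk phantoms of radius
3–12 px. These sizes keep the full suite at a few minutes on one core
while leaving the statistical assertions well-powered; the acceptance
script uses 10⁵-event sorter runs and a 5 × 10³-event end-to-end
experiment. All stochastic entry points take explicit seeds; rendering
uses the ambient RNG unless the acquisition config pins one, so end-to-end
experiments are reproducible from a single seed.

# Known limitations

* Disks-with-droplets is the entire morphological vocabulary; no
  shape-feature validation beyond area is meaningful.
* The synthetic PS/PMMA spectra are caricatures; unmixing performance on
  real spectra depends on their condition number, which the basis
  diagnostics (`show()` on a basis) report.
* The sorter model assumes perfectly predictable sort timing; latency
  jitter is a config extension defaulting to zero.
* Coincident cells within one frame are segmented as one object.
* Classification is gating only; learned classifiers are out of scope.
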