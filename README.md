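# SRSflowSort

A virtual Raman image-activated cell sorter for R.

Image-activated cell sorting with stimulated Raman scattering (SRS)
contrast images every cell crossing a microfluidic channel at four
vibrational wavenumbers, decides in real time whether it is a target, and
deflects decided cells with a dual-membrane push-pull sorter. Designing and
validating such an instrument raises quantitative questions that are hard
to answer on hardware: how does sort purity fall as throughput rises? What
does the coincidence of two cells inside the sort window do to a decided
cell? How accurately does the image pipeline — masking, spectral unmixing,
feature gating — recover ground truth at a given signal-to-noise ratio?

`SRSflowSort` answers these with a fully synthetic, ground-truth-labeled
re-creation of the instrument's computational core, aimed at instrument
builders and computational cytometrists:

* **synthetic acquisition** — Poisson particle arrivals (rate λ, target
  fraction r) rendered as 4-color × 24-pixel line scans at 48 kHz with a
  forward-scatter trigger trace and configurable noise;
* **image pipeline** — threshold event detection, 122-line frame
  construction, square-pixel normalization (122 × 24 → 122 × 89),
  Canny/morphology cell masking, pseudo-inverse spectral unmixing, feature
  extraction and inclusive-boundary gating;
* **sorter model** — the push-pull sorter as an analytic 32-scenario
  Poisson coincidence model and as a Monte-Carlo event-stream simulation;
* **metrics** — event rate, sort purity and yield.

## The model in brief

Per-pixel measurements follow the linear mixing model **d** = **S c**;
unmixing applies the Moore–Penrose pseudo-inverse of the spectral basis
**S**. Event rate uses the 50-event sliding window

&nbsp;&nbsp;&nbsp;&nbsp;e&#8342; = 50 / (t&#8342; − t&#8342;&#8331;&#8325;&#8320;),&nbsp;&nbsp;i ≥ 51.

For Poisson arrivals, a neighbor gap is shorter than the coincidence
half-window τ with probability p = 1 − e^(−λτ). A particle's sort outcome
is determined by five binary factors (its own and both neighbors' target
identities, and whether each adjacent gap is < τ), spanning 2⁵ = 32
scenarios whose probabilities multiply; sort purity is

&nbsp;&nbsp;&nbsp;&nbsp;Purity(λ, τ, r) = ΣP&#8321;&#8346; / (ΣP&#8321;&#8346; + ΣP&#8338;&#8346;)

over the scenarios ending true/false positive. τ derives from the
sorting-region transit, τ = L/v/2, so faster flow trades imaging signal
for purity. Sorted-sample quality uses the count definitions purity =
targets collected / all collected and yield = targets collected / all
targets.

## Worked example

```r
library(SRSflowSort)

basis <- defaultBasis()
basis
#> SpectralBasis: 4 colors x 2 constituents
#>   wavenumbers (cm^-1): 2899, 2954, 3006, 3034
#>   constituents: PS, PMMA
#>   condition number: 1.217

## analytic purity at the two measured operating points (tau = 1.5 ms, r = 0.6)
purityAnalytic(50.2, 1.5e-3, 0.6)
#> [1] 0.9429134
purityAnalytic(85.6, 1.5e-3, 0.6)
#> [1] 0.9063848

## end-to-end: simulate 500 events, image them, gate on the two densities,
## sort with the Monte-Carlo engine, score against ground truth
res <- virtualSortExperiment(nEvents = 500, rate = 50.2,
                             targetFraction = 0.6, seed = 1)
res$accuracy            # gate decisions vs ground-truth species
#> [1] 1
res$sortRun
#> SortRun: 500 events (tau 0.0015 s, alternating rules)
#>   TP=284, FP=13, TN=177, FN=26
unlist(res$metrics[c("purity", "yield")])
#>   purity    yield
#> 0.956229 0.916129
nominalThroughput(res$metrics$eventRate)
#> [1] 50.52929
```

Every gate decision is correct at the reference noise level, yet 13
nontargets still land in the collection and 26 targets in the waste: pure
coincidence losses inside the 3 ms sort window, which is exactly what the
throughput–purity model predicts (94.3% analytic purity at 50.2 events/s
vs 95.6% in this 500-event run).

The same machinery is scriptable from a shell via
`inst/scripts/srsflowsort` (subcommands `simulate`, `process`,
`sort-model`, `evaluate`, `end-to-end`; every run writes a JSON manifest
with seed and checksums).

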