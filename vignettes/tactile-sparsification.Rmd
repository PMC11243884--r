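---
title: "Sparsifying tactile sensor-array recordings with wavelets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsifying tactile sensor-array recordings with wavelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactwave)
```

## The problem

High-density tactile sensor arrays — glove-style grids with hundreds of
taxels sampled continuously — produce dense spatiotemporal pressure streams,
while the interactions they record are localized in both space and time: a
grasp presses a handful of taxels for a few seconds and leaves the rest at
their resting level. A transform in which such recordings become *sparse*
(most coefficients negligible) pays off twice: compressive sampling needs a
sparse basis, and storage/transmission shrink to the few significant
coefficients.

`tactwave` benchmarks candidate sparsifying transforms for this data class.
The candidates are multilevel discrete wavelet transforms (DWT) drawn from a
75-wavelet registry spanning 12 orthogonal and biorthogonal families, plus
the orthonormal type-II discrete cosine transform (DCT) as the conventional
baseline. Each candidate is evaluated in three dimensionalities on a
recording array of shape time × rows × cols:

* **1D** — transform each taxel's time series independently (temporal
  structure only);
* **2D** — transform each spatial frame independently (spatial structure
  only);
* **3D** — one separable transform of the full volume (spatiotemporal).

## The sparsification procedure

A recording is transformed, and the coefficients `w` are quantized to
integer multiples of a step `Q` with truncation toward zero:

```
sparse_rep = Q * trunc(w / Q)
```

Truncation sends every sub-`Q` magnitude to exactly zero — that is the
sparsification mechanism — and never grows a magnitude, so the retained
energy ratio cannot exceed one. The reconstruction error after inverting the
quantized coefficients is measured by the normalized mean square error

```
NMSE = mean((y - y_hat)^2) / mean(y)
```

i.e. the squared error scaled by the *mean* of the original signal. Dividing
by the mean (rather than the mean square) is dimensionally unusual but is
the convention this survey's error targets are defined on, so `nmse()`
implements it exactly as stated; a `variance_normalized` switch provides the
mean-square variant for work on other scales, and the survey never uses it.
One practical consequence: the resting (baseline) level of the array enters
the denominator, so the error targets are anchored to the raw ADC scale.

`search_q()` finds the `Q` that achieves a requested NMSE. The survey
evaluates four targets — 0.01, 0.0043, 0.0015 and 0.0001 — and scores each
converged cell by three metrics:

* **sparsity** — nonzero coefficients over the number of input samples
  (smaller is better);
* **bits per pixel (NBP)** — nonzero count × a sign+magnitude code width
  `1 + ceil(log2(max|k| + 1))` sized by the largest quantization index,
  averaged over all samples. This is a storage *accounting*, not a codec: no
  entropy coding and no positional cost;
* **energy ratio (ER)** — retained squared-coefficient energy relative to
  the unquantized transform.

`run_survey()` executes the full wavelet × dimensionality × target sweep per
recording, averages metrics arithmetically across recordings, and returns a
tibble with one row per cell; `rank_by()` produces the ranked top-k views
and `dct_sparsity_ratio()` the DCT-to-best-wavelet comparison.

## Numerical design of the Q search

Algorithm: bisection on `log Q` between `Q_lo` (machine epsilon times the
largest coefficient magnitude; error ≈ 0) and `Q_hi = 2 max|w|` (every
coefficient quantizes to zero; maximal error), with a default convergence
band of `1e-4 × target` and a 60-iteration budget.

Two refinements matter in practice:

* **Parseval shortcut.** For orthogonal wavelets and the orthonormal DCT on
  unpadded inputs, the reconstruction error equals the coefficient-domain
  error exactly, so each bisection iterate costs one vector pass instead of
  an inverse transform. The discrete Meyer filter is excluded (its truncated
  filters are only approximately orthogonal); biorthogonal wavelets take the
  inverse-transform path. The final reported NMSE is always recomputed from
  the actual reconstruction at the final `Q`.
* **Staircase solver.** NMSE as a function of `Q` is a dense staircase:
  every time some `w/Q` crosses an integer the error jumps, and near-plateau
  teeth can be wider than the convergence band, stranding plain bisection
  close to — but outside — the band. Between crossings the index assignment
  `k = trunc(w/Q)` is fixed and the squared error is an exact quadratic in
  `Q`, so when bisection stalls the search solves that quadratic in closed
  form and iterates as the assignment updates. On full-size recordings this
  lands within ~1e-11 of the target. A search that still cannot reach the
  band is returned flagged `converged = FALSE`, never silently as converged.

Related caveat: ER is *not* pointwise monotone in `Q`. Truncation gives
`|Q trunc(w/Q)| ≤ |w|`, hence ER ≤ 1, but as `Q` grows a coefficient can
land back on an exact multiple and briefly regain energy; with one dominant
coefficient the excursion can be large. Sparsity, in contrast, is exactly
non-increasing in `Q` (`#{|w| ≥ Q}`), and the tests assert precisely these
two facts.

## Transforms

The DWT is a cascading two-channel filter bank: convolve with the
decomposition low/high-pass pair, downsample by two, and iterate the
low-pass branch `N = floor(log2(L))` times, where `L` is the transform-axis
length (1D) or the smallest transformed dimension (2D/3D). Signal extension
is **periodized** (circular), so the coefficient count equals the sample
count and the sparsity denominator is unambiguous; this is the only
extension mode the package implements, because every metric's denominator —
and the registry-wide perfect-reconstruction property the tests assert —
is only clean under it. Non-dyadic lengths are handled by replicating the
final sample at the affected level (at most one extra coefficient per
level). 2D and 3D transforms are separable with orientation-major subband
order; the flattening order (approximation, then detail levels coarsest to
finest) is fixed and documented because the top-k tie-break depends on it.

Filter taps for the classical families (Haar/Daubechies, Symlets, Coiflets,
spline biorthogonal pairs and their duals) are the standard published
coefficient tables, stored as plain text in `inst/extdata`. The discrete
Meyer filter is constructed by frequency sampling the Meyer low-pass
response and truncating to the conventional 102 taps; being an FIR
truncation of an ideal filter it reconstructs to about `2e-6` relative
rather than the `1e-11` of the other families, and the tests bound it
separately. The Beylkin and Vaidyanathan filters are published tables
verified against the orthonormality conditions at load-test time. Four
families (Fejér–Korovkin, best-localized Daubechies, Morris
minimum-bandwidth, Han linear-phase moments — 17 of the 75 names) have no
published-tap source available to this package; they are listed in the
registry flagged `implemented = FALSE`, and `wavelet_filter()` refuses them
with an error naming the family, so the gap is explicit rather than
approximated.

## The synthetic grasp generator

`grasp_model()` + `generate_dataset()` produce seeded recordings with the
statistical structure the survey exploits, so the whole pipeline runs with
no external data. What it emulates, with defaults in parentheses:

* a 32 × 32 grid carrying 548 active taxels (the tactile-glove layout
  class); the mask is the top-548 cells of a smoothed seeded random field,
  because physical taxels form contiguous patches, and it is a fixed
  property of the array across trials;
* a grasp event of about 5 s within an 8 s recording at 16 Hz: a
  difference-of-logistics temporal bump (rise/fall constant 0.4 s), exactly
  zero outside `[onset, offset]`, shared by all taxels;
* spatially compact contact: 2–3 Gaussian blobs (σ ≈ 2.5 taxels) seeded on
  the active region, peak 400 ADC counts above rest;
* a resting level of 500 counts on active taxels. Resistive arrays rest
  mid-range, and because the NMSE denominator is the raw-signal mean the
  resting level fixes where the error targets sit relative to the sensor
  noise floor — omitting it would push all four targets below the noise
  floor and invert the survey's operating regime;
* Gaussian sensor noise (sd 2 counts) on active taxels, then clipping to
  `[0, 1023]` and integer rounding (10-bit ADC);
* per-trial jitter of onset (sd 0.3 s), amplitude (10%) and blob centers
  (1 taxel); zero jitter reproduces bit-identical trials.

Preprocessing mirrors the study design: a second-order Butterworth low-pass
at `fs/7`, applied per taxel. The filter family, the zero-phase
forward–backward application (over odd-reflection padding so the state has
settled at both ends) and the interpretation of the pass-band edge are
choices the source description leaves open; they are explicit arguments
(`order`, `cutoff_fraction`, `causal`) with the least-surprising defaults.

**What passing tests show — and do not show.** The generator reproduces the
*structural* premises: spatiotemporal locality, smooth low-frequency
temporal profiles, a dominant resting level, 10-bit integer data. On it, the
package reproduces the qualitative dimensionality finding (1D sparsest, then
3D, then 2D) and 1D sparsities of the right order (~1%). It does **not**
reproduce per-object grasp signatures, sensor-to-sensor gain variation, or
the micro-dynamics of real grasp adjustments. One visible consequence: the
synthetic temporal bump is so smooth and so global in time that the 1D DCT
matches or slightly beats the best 1D wavelet on synthetic data, whereas on
real tactile recordings — with sharper, more localized transients — wavelets
win by a large factor. Survey *rankings* computed on synthetic data
therefore validate the machinery, not the real-data conclusions.

## Diagnostics

* `topk_reconstruction_curve()` — keep the k largest-magnitude coefficients
  (ties resolved by the earlier position in the documented flattening
  order), invert, and score NMSE/PSNR: the compactness (phase-transition)
  view. At `k = 0` the NMSE equals `mean(y^2)/mean(y)` identically.
* `spatiotemporal_error_profile()` — the pooled NMSE recomputed per sensor
  over time and per frame over space. The per-slice normalization divides by
  each slice's own mean, so slice profiles only average back to the pooled
  value when all slices share a mean; zero-mean slices are excluded and
  counted rather than hidden.
* `grand_average_interaction()` — per-recording activity (pressure above
  each taxel's resting median, summed over the mask), aligned at onset
  (first frame above 10% of the trial's peak — the alignment rule is a
  package choice), resampled and averaged.
* `filter_length_vs_sparsity()` — OLS of sparsity on filter support length
  with the standard 95% CI of the slope.
* `scaling_similarity()` — maximal normalized cross-correlation over shifts
  between a wavelet's iterated scaling function (cascade algorithm, 5
  iterations) and a temporal template. Reported signed, as a descriptive
  quantity.

## Problem sizes used by the shipped tests and scripts

The test suite exercises unit properties on 16 × 16-grid, 4 s fixtures and
the end-to-end checks on the full 32 × 32, 8 s model (10-trial dataset,
10-wavelet reduced registry, target 0.01); `scripts/acceptance.R` runs the
same full-size reduced survey. These sizes were chosen so the whole suite
completes in minutes on a laptop while keeping every end-to-end claim at the
full default geometry. On the small fixtures the quantization staircase is
coarse relative to the default convergence band, so those unit tests pass an
explicit `1e-3 × target` tolerance; the strict `1e-4 × target` contract is
asserted at full size.

## Known limitations

* The four MATLAB-only wavelet families noted above are registered but not
  implementable here; rankings that would feature them (e.g. some
  minimum-bandwidth candidates) are computed without them.
* NBP is an accounting convention; absolute NBP values are only comparable
  under the same convention.
* Periodized extension differs slightly from symmetric-extension toolboxes
  near array borders; cross-toolbox coefficient comparisons should use the
  shipped reference fixtures.
* The survey averages metrics arithmetically across recordings; pooling the
  whole dataset into one error computation is a defensible alternative that
  would shift absolute values slightly.
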