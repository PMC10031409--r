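---
title: "Microwave stroke monitoring with sinc wavelet-matched filter banks"
author: "mwstroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave stroke monitoring with sinc wavelet-matched filter banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwstroke)
```

## The measurement model

A stroke changes the dielectric contrast of brain tissue, and a wideband
microwave array can sense that change non-invasively. The set-up this
package models is a hemi-elliptical ring of `L = 16` antennas around the
head; each antenna works mono-statically, radiating a stepped-frequency
sweep of 401 equidistant points over 1.1–3 GHz and recording the complex
reflection coefficient S11(f). Antenna 1 sits on the left/right symmetry
axis of the head, so antenna `i` and antenna `L + 2 − i` are mirror images
(the index formula degenerates at `i = 1`; the two axis antennas, 1 and
`L/2 + 1`, are their own mirror — the only reading under which the
mirror-subtraction approach yields the expected `L/2` independent
responses).

The sweep is transformed to the time domain by embedding the band-limited
coefficients at their absolute frequency bins of a conjugate-symmetric
spectrum and inverse-FFT-ing; the sample period is `1/(n_fft · Δf)`. No
window is applied by default: the radiated signal is rectangular in
frequency, and the matched filter downstream is built precisely for that
band shape. A Hann taper is available for users who prefer lower sidelobes
over matched-filter fidelity.

## Background removal

The air–skull reflection dominates the record; five subtraction approaches
estimate the internal target response, with circular adjacency (antenna
`L`'s neighbour is antenna 1) used throughout:

| approach | background estimate at antenna `i` | character |
|---|---|---|
| App-1 | same patient's healthy baseline | ideal, needs a prior record |
| App-2 | adjacent antenna `i − 1` (wrap at 1) | differences out slow spatial structure |
| App-3 | mirror antenna `L + 2 − i` | exactly antisymmetric; `L/2` independent responses; optional negative clipping restores `L` usable series |
| App-4 | mean of all antennas, or of the `2k` circular neighbours excluding `i` | neighbour size `k` exposed because the source formulation leaves it open |
| App-5a | mean of antennas `i+1`, `mirror(i)`, `mirror(i+1)` | novel; breaks the App-3 antisymmetry |
| App-5b | mean of `mirror(i)`, `mirror(i+1)` | two-signal variant |

In App-5a the third averaged signal is read as the mirror of antenna
`i + 1` (index `L + 1 − i`); the printed form of the estimator is ambiguous
and this is the reading consistent with its companion variant. App-5 is
computed as an average of pairwise differences rather than
`x − mean(...)`, so that identical inputs produce an exactly zero response
in floating point — a property the null tests rely on.

All approaches are linear; App-3 with clipping is the one documented
nonlinearity.

## The wavelet-matched filter bank

The mother wavelet is the normalised sinc truncated to `T` samples
(default 33) symmetrically around its main lobe and shifted onto
`0..T−1`, so the peak of 1 sits at the centre sample and zero crossings at
the other integer offsets. The printed construction applies the `T/2`
shift twice; the implementation follows the stated intent — truncate about
the main lobe, shift once onto positive indices. A `zero_mean_sinc`
convention subtracts the sample mean, restoring the zero-DC property of
the physical band-pass pulse; the plain sinc remains the default for
fidelity to the construction as published.

Scaled filters evaluate `ψ(n/α)` directly on the integer grid covering
`[0, α(T−1)]` — no interpolation, so non-integer scales are exact. The
prefactor is `1/√α` by default (`l2`, energy-comparable across scales) with
`1/α` (`l1`) selectable, because the printed prefactor is typographically
ambiguous between the two; both readings are reproducible. The default
bank uses 64 linear scales from 1 to 64 and one shift per sample, covering
low- and high-frequency content; the transform zero-pads outside the
signal support because the physical signal is zero before the first echo.
The production path computes each scale by FFT cross-correlation and is
tested to 1e-10 against a naive double-loop summation.

## Metrics

* **Relative wavelet energy** `E(τ,α) = |C|²/ΣΣ|C|²`. An all-zero grid (a
  healthy brain after perfect background removal) returns zeros with a
  degenerate flag rather than an error.
* **Shannon wavelet entropy**, two forms. `as_printed` is the literal sum
  `Σ |C|² log₂|C|²` with `0·log 0 := 0` — scale-dependent, kept as the
  default for fidelity. `normalized_shannon` normalises each scale row (or
  time column) to a probability vector first and is invariant to uniform
  scaling of `C`. Both are stored in every metrics bundle and labelled.
* **Opposite-antenna energy distance**
  `ω_α^i = Σ_τ log₂(|C|²_i/|C|²_mirror)`. Squared coefficients are floored
  at `epsilon` (default 1e-300, configurable) so zero cells stay defined;
  the distance is computed as a sum of log differences, which makes the
  antisymmetry `ω^i = −ω^{mirror(i)}` exact at the bit level.

## Diagnosis

Ranking methods:

* `distance` — score `Σ|ω_α| + Σ|ω_τ|`. Mirrored antennas tie exactly on
  this score (their profiles are negations), so the tie is resolved by the
  signed profile sum — the antenna whose energy exceeds its mirror's, i.e.
  the stroke side — and only then by ascending antenna id. Resolving the
  tie by id alone would systematically mislocate strokes in one half of
  the head.
* `energy` — descending total wavelet energy.
* `entropy` — ascending normalised-Shannon scale entropy, summarised per
  antenna by the **minimum** of the per-scale entropy vector (the entropy
  at the best-matched scale). An unweighted mean was evaluated and
  rejected: scale rows that hold nothing but the noise floor have
  near-maximal entropy for every antenna and wash out the inverse
  energy–entropy relationship the ranking exploits.

Detection declares a stroke when the top score exceeds the median score by
a configurable contrast ratio (default 2). Several rankings may be
combined; the report then aggregates them by Borda count. The rule is a
formalisation of reading "variance in the results" off the plots; it is
deliberately simple and every threshold is configurable.

## The synthetic phantom

Real phantom measurements of this kind are proprietary, so the package
ships a point-scatterer simulator whose structure matches what the five
approaches assume:

* a unit-amplitude air–skull echo delayed by the two-way standoff path.
  It is identical across antennas — constant standoff on a uniform ring —
  which makes the clutter-free healthy background exactly mirror-symmetric
  and lets App-3 **and** App-5 null it exactly. The left/right-asymmetric
  per-antenna variation seen in practice is carried by the clutter term;
* when a stroke is present, a weak echo per antenna with delay
  `2(standoff/c + d·√ε_r/c)` (in-tissue speed `c/√ε_r`) and amplitude
  `reflectivity · exp(−d/attenuation_length)`, `d` the skin-to-stroke
  distance;
* smooth per-antenna clutter: a degree-3 random complex polynomial over
  the band, scaled to `clutter_level` — structured reflections, not white
  noise;
* white complex measurement noise per (antenna, frequency) point.

Parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `L`, band, points | 16, 1.1–3 GHz, 401 | the measurement system's stated set-up |
| semi-axes | 0.09 × 0.07 m | adult head cross-section |
| standoff | 0.01 m | near-field contact array |
| `stroke_reflectivity` | 0.05 | weak echo relative to the skull return |
| `effective_permittivity` | 45 | one-parameter homogeneous surrogate for the four-tissue head; controls echo delay realistically |
| `clutter_level` | 0.01 | structured residuals an order below the main echo |
| `noise_level` | 0.005 | VNA noise floor at half the clutter level |
| `attenuation_length` | 0.05 m | tissue loss making near antennas record visibly stronger echoes |

`paired_scenario()` gives the App-1 input pair: both sweeps share the
clutter realization (the set-up is unchanged between visits) and carry
independent noise, so baseline subtraction isolates the stroke echo
exactly in the noiseless limit.

The generator does **not** emulate: finite stroke size (the inclusion is a
point scatterer), tissue dispersion, multiple scattering, antenna
patterns, or calibration artefacts. A green pipeline test therefore
establishes internal consistency of the method chain on a signal model
with the right symmetry and delay structure — not clinical performance.

## Numerical choices

* Frequency grids must be equidistant within 1e-6 relative; the internal
  unit is always Hz. Touchstone input accepts RI/MA/DB and HZ→GHZ
  prefixes; output is always lossless RI.
* Text artifacts (sweeps, responses, metric grids) are written with
  `%.17g`, which round-trips IEEE doubles bit-exactly.
* `n_fft = "auto"` picks the smallest power of two accommodating twice the
  highest band bin.
* Ties in every ranking break deterministically (signed sum, then id).
* Seeds: the simulator uses a local RNG state and never perturbs the
  caller's random stream; derived seeds stay below 2³¹.

## Known limitations

* The summed-magnitude distance score localizes well when the stroke lies
  in the high-asymmetry region facing the array's lateral antennas — the
  configuration the method was demonstrated on — but not for strokes near
  the symmetry axis: the mirror of a near-axis antenna is itself close to
  the stroke, the asymmetry the statistic feeds on vanishes, and the two
  axis antennas score exactly zero by construction. Over uniformly drawn
  stroke positions the energy ranking is the far more reliable localizer;
  the acceptance suite records this honestly.
* The literal entropy form is scale-dependent; cross-run comparisons
  should use the normalised form.
* The detection contrast rule has a heavy-tailed null distribution when
  responses are pure noise; with a noiseless healthy baseline it is exact.
  Threshold calibration against a measured noise model is out of scope.
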