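---
title: "ndRMS electrode-density analysis: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ndRMS electrode-density analysis: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndrms)
```

## The statistic

For a pair of electrodes, each trial signal is z-normalized —

$$\mathrm{trial}_{norm}(n) = \frac{\mathrm{trial}(n) - \mu_{trial}}{\sigma_{trial}}$$

— and the ndRMS is the root mean square of the difference of the two
normalized signals,

$$\mathrm{ndRMS} = \sqrt{\tfrac{1}{N}\sum_{n=1}^{N} \Delta \mathrm{trial}_{norm}(n)^2}.$$

Algebraically this equals $\sqrt{2(1-r)}$ with $r$ the Pearson correlation
of the pair, which fixes the interpretation scale: 0 for identical signals,
$\sqrt{2}$ for uncorrelated signals (independent white noise), 2 for
oscillations in antiphase. For two equal-frequency sinusoids observed over
an integer number of cycles the statistic is exactly $2\,|\sin(\varphi/2)|$
in the phase lag $\varphi$, which is what makes values above $\sqrt 2$
diagnostic of out-of-phase oscillatory activity. Because each trial is
normalized before differencing, electrode impedance (hence contact size)
and the power-law fall of signal amplitude with frequency drop out, and
pairs are comparable across grids and bands.

Two aggregation modes mirror the two recording situations the pipeline
serves. For awake task recordings, the ndRMS is computed per rest trial and
summarized per pair as the **median** over trials (robust to outlier
trials; the midpoint of the two central values for even counts). For
recordings under general anesthesia there are no trials and the ndRMS is
computed **once across the entire stream**. Per-pair summaries are then
averaged over all equidistant pairs — distances rounded to 0.1 mm define
"equidistant" — and only inter-electrode distance (IED) bins holding at
least ten pairs are kept. Recording-level curves are averaged over task
repetitions per participant, and participant curves are averaged into group
curves only for bins present in at least two participants.

### Numerical choices

* **Population (divide-by-$N$) standard deviation** in the z-normalization.
  The theoretical bounds and the $\sqrt{2(1-r)}$ identity then hold exactly
  at finite trial length, not just asymptotically; with the sample
  denominator the antiphase bound would be missed by $O(1/N)$.
* **Degenerate trials.** A constant (or numerically constant, $\sigma <
  10^{-12}$ of the series scale) trial cannot be normalized. Such
  pair-trials are excluded from the median rather than assigned a value;
  a pair is dropped entirely if more than half of its trials are
  degenerate. This is a package decision — the definition of the statistic
  is silent about zero-variance input.
* **Bin labelling.** Distances are rounded to the nearest 0.1 mm, so the
  3 mm lattice diagonal ($3\sqrt2 = 4.2426$) labels as 4.2 mm, and the
  hexagonal $0.9\sqrt{12} = 3.118$ as 3.1 mm.

## Grid geometry

The HD default is an 8 × 12 square lattice at 3 mm pitch with 1 mm exposed
contacts; the UHD default is a 4 × 8 grid at 0.9 mm pitch with 0.2 mm
contacts. The UHD lattice type is selectable and defaults to hexagonal:
a 0.9 mm *square* lattice has no pair distances near 3.1 mm or 4.1 mm
(no integer solutions of $a^2+b^2 \approx 11.9$ or $20.8$), whereas the
hexagonal lattice produces exactly $0.9\sqrt{12} \approx 3.118$ and
$0.9\sqrt{21} \approx 4.124$ — the two distances at which HD and UHD grids
can be compared (3.0 vs 3.1 mm and 4.2 vs 4.1 mm with the default 0.2 mm
matching tolerance). This inference from the comparable distances is
documented here rather than asserted as a manufacturer fact. Layouts are
planar; cortical curvature and sulcus-crossing pairs are out of scope.

## The grid comparison

At each matched IED the two grids are compared with a two-sided Wilcoxon
rank-sum test on their per-band values — the eight dyadic bands (1–4,
4–8, 8–16, 16–32, 32–64, 64–128, 128–256, 256–499 Hz) plus the unfiltered
series, so nine values per grid at group level. The reported statistic is
the **sum of ranks of the lower-ranked sample**; under complete separation
of two nine-value samples this gives $W = 45$ with exact two-sided
$p = 2/\binom{18}{9} = 4.11\times 10^{-5}$. That $W=45$ is only attainable
with $n=m=9$ is why the nine-per-band reading of the comparison was
adopted. P-values are exact for $n, m \le 12$ without ties (midranks and a
normal approximation with continuity correction otherwise) and are
Bonferroni-corrected by the number of matched IEDs.

## Preprocessing

The stage order is fixed: bad-channel masking → notch filtering → common
median reference → band operations → segmentation. Filtering runs on the
continuous recording *before* segmentation: rest trials of 1–1.75 s are too
short for clean 1–4 Hz filtering, and zero-phase filtering of the
continuous data confines edge effects to the recording boundaries.

* **Bad channels** are flagged as *flat* (sd < 1e−8 µV), *amplitude*
  (robust amplitude more than 5 scaled MADs from the cross-channel
  median; flat channels are excluded from this comparison), *line_noise*
  (50 ± 1 Hz power above half the 1–499 Hz total), or *outliers* (more
  than 1% of samples beyond 5 sd). The thresholds are declared package
  defaults, all configurable — the source method they adapt does not
  publish values — and a channel report is always emitted to support
  visual confirmation.
* **Notch filtering** removes 50 Hz mains and a 24 Hz operating-room
  artifact with all integer harmonics up to 499 Hz (the top analysis band
  edge), each with a 4th-order Butterworth band-stop at ±1 Hz.
* **Band-pass** uses order 3 for the 1–4 and 4–8 Hz bands and order 4 for
  the higher bands; the "unfiltered" band is an identity sentinel. The
  acquisition-side 0.3–500 Hz band-pass is treated as a property of the
  recording, not re-applied.
* **Zero-phase application.** Whether the original filters were zero-phase
  is not stated; filters here run forward–backward because a one-directional
  pass would add frequency-dependent phase lag that biases the ndRMS (a
  pure delay between identical signals already produces a nonzero value).
  Stated orders refer to the designed filter before the backward pass.
* **Second-order sections.** Narrow band filters (a ±1 Hz stop at 2000 Hz
  sampling) are numerically unusable as order-8 direct-form polynomials:
  factoring or running them amplifies rounding to percent level and the
  factored roots can land outside the unit circle. Filters are therefore
  designed analytically — Butterworth prototype poles, analog band
  transform, bilinear map per pole — and applied as cascaded biquads, each
  normalized to unit gain at its reference frequency, with odd-reflection
  edge padding scaled to the filter's transient length. Linearity then
  holds to ~1e−12 and a 10 s, 50 Hz sinusoid is attenuated to 1.3% RMS.
  A residual edge response within ~1/bandwidth of the recording ends is
  unavoidable for any finite signal and is why band rejection is asserted
  on the signal interior in the tests.
* **Morlet band power** (used for the correlation analysis and the task
  map, not for the ndRMS) averages squared coefficient magnitudes over
  five log-spaced centre frequencies per band with 7-cycle wavelets —
  both unstated upstream, chosen as conventional values; both are
  arguments.
* **Segmentation** supports the two published schemes: `half_isi` (rest =
  half the inter-stimulus interval before stimulus onset, active = half
  after) and `fixed_1p5s` (1.5 s windows) with half-open sample intervals,
  so every trial has exactly `round(duration * fs)` samples; trials
  exceeding the recording bounds are dropped.

## The forward simulator

No generative model of the original data exists, so the simulator is
artifact design: it emulates the three mechanisms the analysis is sensitive
to, with controllable shares.

1. **Traveling oscillations** — planar waves whose phase advances at a
   cortical conduction speed (defaults 2.5 m/s, within the 2–3 m/s range of
   short-range sensorimotor transmission). These are the shared sources:
   their phase lag grows linearly with distance, driving the ndRMS up with
   IED according to the $2|\sin(\varphi/2)|$ law.
2. **Broadband activity** — sources on a dense lattice with a
   $1/f^{\alpha}$ *power* spectrum ($\alpha = 2$ by default, the
   conventional power-law exponent for epicortical spectra; the spectrum is
   flattened below 1 Hz), optionally spatially correlated over a Gaussian
   length, mixed into the electrodes by an exponential volume-conduction
   kernel $e^{-d/\lambda}$. Mixing is a normalized weighted average, so
   coherent oscillations keep their amplitude while dense independent
   broadband is attenuated by spatial integration, as physical volume
   averaging would.
3. **Sensor noise** — independent white noise per electrode, added after
   disc averaging (amplifier noise does not average over the contact).

Electrodes sample the field as the mean over a deterministic sunflower
pattern of points on the exposed disc (12 by default; 1 = centre only), so
electrode-size effects are seed-independent. All randomness flows from one
seed with a fixed split (sources: `seed`; sensor noise: `seed + 1`; task
modulation: `seed + 2`), making every dataset byte-reproducible.

### Default study conditions

`sim_config()` defaults define the simulated condition used throughout the
tests: 2000 Hz sampling, 8 s duration, oscillations at 10 Hz (amplitude
1.0) and 22 Hz (amplitude 0.6) traveling at 2.5 m/s in orthogonal
directions, broadband amplitude 6 with 0.5 mm correlation length on a 1 mm
source lattice, conduction length λ = 2 mm, sensor noise sd 0.4. The
durations are desk-scale choices: long enough that per-pair correlation
estimates are stable (a few thousand effective samples), short enough that
a full 96-electrode simulation stays in seconds. Under these conditions
the mean ndRMS of an HD grid rises monotonically with IED (Spearman rank
correlation across bins > 0.9), reproducing the qualitative distance
profile of intraoperative grids.

The **electrode-size condition** is separate, because contact-size effects
live at the sub-millimetre scale: a fine-scale field (λ = 0.4 mm, source
spacing 0.2 mm, broadband amplitude 10, one shared 10 Hz oscillation,
noise sd 0.1) on a small pitch-3 grid, sampled with 1 mm vs 0.2 mm discs
over 3 s replicates. Larger discs average away more of the fine-scale
broadband while keeping the shared oscillation, so their pairwise ndRMS at
matched IED is systematically lower — the direction observed when UHD
grids record larger ndRMS than HD grids at the same spacing.

### What the simulator does not emulate

Cortical folding (sulcus-crossing pairs), laminar source geometry, spiking,
anesthesia pharmacodynamics, electrode impedance spectra, amplifier
filtering, and non-stationarity. Passing tests on simulated data therefore
demonstrate that the *analysis machinery* recovers known ground truth —
bounds, monotone distance profiles, size effects, calibrated test
statistics — not that real cortex satisfies the simulator's assumptions.

## Task-response mapping

Per-trial mean 64–128 Hz Morlet power is correlated with a binary
rest/active regressor; the map reports $\mathrm{sign}(r)\,r^2$ per channel
with two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees
of freedom ($|r|=1$ maps to $p=0$). Significance is Bonferroni-corrected by
the number of channels entering the analysis (good channels); zero-variance
channels are reported untested and deliberately do *not* shrink the
Bonferroni denominator. Raw power is correlated by default with a log
option, since the upstream analysis does not state a transform. A
label-permutation null of this test keeps the false-positive rate at the
nominal 5%.

## Interfaces

Recordings travel as a raw little-endian float64 matrix with a JSON sidecar
(lossless round trip, unlike a 16-bit export), electrode tables and events
as BIDS-style TSV, results as tidy TSV (`level, participant, repetition,
ied_mm, band, statistic, value, n`) with provenance headers (package
version, seed, configuration hash), and comparisons as structured objects.
`run_pipeline()` executes the fixed stage order from an `analysis_config`
and logs per-stage counts; reruns with the same configuration are
byte-identical. The `exec/ndrms` script exposes `simulate` and `run` for
shell use; all other operations are single exported function calls.

## Known limitations

* The distance-resolved curves of real intraoperative grids cannot be
  reproduced here — the package validates against analytic anchors and
  simulated ground truth instead.
* The UHD hexagonal lattice is an inference from the comparable distances,
  not a specification.
* Bad-channel thresholds are package defaults, not published values.
* Edge response of the zero-phase filters extends ~1/bandwidth into the
  recording ends; with filtering applied before segmentation this affects
  only the first and last trials of very short recordings.
* The exact rank-sum path requires tie-free samples; ties fall back to the
  midrank normal approximation, which is inaccurate below ~8 values per
  sample.
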