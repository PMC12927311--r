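---
title: "Chirp EFR analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chirp EFR analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efrchirp)
```

This vignette is the package's own account of the science it implements:
the stimulus model, the time–frequency measures, the extraction and
statistics conventions, what the synthetic cohorts do and do not emulate,
and the numerical choices that an analyst should know about before
trusting (or comparing) results.

## The stimulus and its frequency-to-time mapping

The stimulus is a click train whose instantaneous repetition rate sweeps
down from 60 Hz to 30 Hz and back up, in 1-Hz steps: each grid frequency
$f$ occupies exactly one period $1/f$ of the train. Cumulative sums of
$1/f$ therefore assign a time to every frequency in each sweep:

```{r}
tl <- chirp_timeline(frequency_grid(30, 60, 1))
tl$duration          # = 2 * sum(1/f), f = 30..60  ->  ~1.44 s
head(tl$stimulus, 3)
```

Two conventions coexist for "the time of frequency $f$": the cumulative
value itself (the *end* of $f$'s own period; the literal reading of the
procedure) and the period's *onset* (cumulative value minus $1/f$). Both
are carried in the timeline; response-curve windows default to the
cumulative (`anchor = "cumsum"`) convention and accept
`anchor = "onset"`. The difference moves every analysis window by one
period (16–33 ms) and has no visible effect on group-level results, but
it does shift single-subject peak estimates by up to 1 Hz, which is why
both are exposed.

`click_train()` renders the stimulus as 1.5-ms uniform-noise bursts at
the mapped times (62 clicks for the default grid), mainly for plotting
and for checking inter-click intervals; sound-level calibration is out of
scope.

## Time–frequency decomposition

Epochs are decomposed with complex Morlet wavelets at the 31 stimulation
frequencies, `n_cycles = 14`, i.e. $\sigma_t = 14/(2\pi f)$ (74 ms at
30 Hz), truncated at $\pm 3\sigma_t$. Two normalization contracts hold
simultaneously:

* the kernel itself is L2-normalized ($\sum |w|^2 = 1$), and
* coefficients are divided by the kernel's response to a unit-amplitude
  sinusoid at its own center frequency ($0.5\sum|w|$), so a unit
  sinusoid yields $|X| \approx 1$ at *every* analysis frequency.

The second contract is what makes PLI/ERSP values comparable across the
30–60 Hz curve; plain L2 normalization alone would scale coefficient
magnitude as $1/\sqrt{f}$. Because the original toolbox's normalization
is not part of the procedure description, absolute (raw) ERSP magnitudes
are only defined up to a scale factor; this cancels under relative
baseline normalization, which is the scale on which results are
reported.

Convolution is computed per trial in the frequency domain (identical to
direct convolution within 1e-9, which the suite asserts) in
trial-batched chunks, so memory stays bounded for large cohorts.
Coefficients closer than half a kernel length to an epoch edge are kept
but flagged invalid; every averaging window (baseline included) must lie
inside the valid region, otherwise the package refuses rather than
silently averaging edge artifacts. With the default −1…2 s epochs, the
−0.5…0 s baseline and all stimulus windows are valid at every analysis
frequency.

## PLI, ERSP and baseline normalization

For $N$ trials with coefficients $X_n(f,t)$ and phases
$\varphi_n = \arg X_n$:

$$\mathrm{PLI}(f,t) = \frac{1}{N}\left|\sum_{n=1}^{N}
  e^{i\varphi_n(f,t)}\right|, \qquad
  \mathrm{ERSP}(f,t) = \frac{1}{N}\sum_{n=1}^{N} |X_n(f,t)|^2.$$

Raw PLI lies in [0, 1]; its floor for finite $N$ under random phases is
$E[\mathrm{PLI}] \approx \sqrt{\pi}/(2\sqrt{N})$ (0.063 at $N = 200$), a
useful sanity value when reading raw maps. Both measures are divided by
their mean over the −500…0 ms window, per channel and per frequency
(`scope = "per-frequency"`); a single-scalar-per-channel alternative
(`scope = "global"`) is available because the procedure's phrase "all
values" admits either reading, but per-frequency division is the
standard relative baseline in time–frequency analysis and is required
for curve shapes to be scale-free. Raw maps are always retained
alongside normalized ones.

A zero-magnitude coefficient has no phase and raises an error in `pli()`
rather than being patched over; it cannot occur once any noise is
present.

## Response curves, IGF and laterality

For each grid frequency the measure map is averaged over the ROI
channels and over two half-open 150-ms windows, one anchored at the
frequency's down-sweep time and one at its up-sweep time — 300 ms of
data per frequency. Both windows count fully even where they overlap in
time (they do near the sweep turnaround, where periods are longest);
de-duplicating the overlap would weight the two sweeps unequally.
Channel averaging happens after the per-channel measure is computed,
matching the convention of averaging PLI/ERSP values over the ROI.

The IGF is the curve's argmax, with ties broken to the lowest frequency
for determinism; the companion value at 40 Hz is a grid lookup, never an
interpolation. The laterality index at a frequency is
$(L - R)/(L + R)$ with $L, R$ the curve values of the mirrored
three-channel ROIs; it is antisymmetric under swapping hemispheres and
confined to [−1, 1].

## The synthetic cohorts

`simulate_epochs()` builds each trial as 1/f^α Gaussian background noise
plus an evoked oscillation active only during the stimulus: its
instantaneous frequency is the stimulated frequency (piecewise constant,
phase reset at each period), its per-trial phase offset is von
Mises(0, κ) — so the noise-free PLI converges to the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$ — and its amplitude follows a Gaussian tuning
$A\exp(-(f - \mathrm{igf})^2 / 2\,\mathrm{bw}^2)$ scaled by a per-channel
topographic gain (fronto-central channels 1.0, others 0.3 by default).
Defaults: sampling rate 1000 Hz, epochs −1…2 s, 200 trials, α = 1,
tuning bandwidth 6 Hz. Per-subject random streams are derived from the
master seed and the subject id, so editing a cohort's membership never
perturbs the remaining subjects.

What the generator deliberately does *not* emulate: volume conduction
and spatially correlated noise, eye/muscle artifacts, adaptation across
the 200 repetitions, variable trial counts after artifact rejection, and
continuous-phase (non-reset) entrainment. Passing tests therefore
validate the *analysis machinery* — they do not certify performance on
real recordings, where these nuisances are present.

The two-group study replica (`study_config()` / `run_study()`) encodes a
weaker, less phase-locked female-like group (κ = 0.9, amplitude 1.4 µV)
and a stronger male-like group (κ = 1.5, amplitude 1.85 µV) over a noise
floor of 3 µV, with the *same* IGF distribution (rounded
Normal(40, 6) Hz clipped to the grid) in both groups. The κ/amplitude
defaults were calibrated once so the groups' raw band-average PLI sits
near 0.24 vs 0.34 — the regime implied by reported normalized group
means — and are not tuned per experiment. The default `"desk"` profile
runs the full 42 + 38 subjects with 100 trials at 200 Hz (a few minutes
on one core); `"full"` restores 200 trials at 1000 Hz.

## Statistics

Group comparisons use the Wilcoxon rank-sum test reported as a signed z
(negative when the first group is weaker), with tie-corrected variance
and a 0.5 continuity correction (exposed as an option, since published z
values rarely state it; it moves p in the third decimal at n ≈ 40).
Paired IGF comparisons use the signed-rank test with zeros dropped.
Per-frequency p values are Bonferroni-corrected with m = 31 and masked
at corrected α = 0.05. Spearman correlations are Pearson correlations of
average ranks with a t-approximation p. The chi-square test of
independence is Pearson's without continuity correction (df = 1). The
normal approximations were chosen because the target sample sizes
(38–42 per group) are far beyond exact-computation need; the test suite
nevertheless checks them against exhaustive permutation and sign-flip
enumerations at n ≤ 8, where the computed worst-case approximation gap
is 0.2 (typical < 0.05, and ~0.002 at n = 42/38), and verifies
family-wise error control of the corrected battery by simulation.

## Numerical conventions and degenerate inputs

* Windows are half-open $[t, t + 150\,\mathrm{ms})$; window sample
  counts are exact when 150 ms is an integer number of samples (e.g.
  200, 500, 1000 Hz).
* Argmax ties break to the lowest frequency; 40 Hz absent from a grid
  reports `NA`, never an interpolated value.
* All-identical samples give z = 0, p = 1; all-zero paired differences
  give p = 1; zero rank variance makes Spearman's rho undefined (NA with
  a warning); zero margins and non-positive expected counts are errors.
* Baseline means below 1e-12, windows outside the valid region, ROI
  channels missing from the data, and non-finite samples are all hard
  errors with explicit messages.

## Known limitations

* **Edge bias of IGF estimates.** The 14-cycle wavelets (~0.4 s) smooth
  over several chirp periods, and near the sweep turnaround the lowest
  frequencies are stimulated twice within one wavelet width. As a
  result, resonances at the grid edges are systematically mis-assigned
  regardless of SNR: sources at 32–34 Hz are pulled to 30–31 Hz (the
  turnaround concentrates their energy under the lowest-frequency
  windows), and sources at 55–58 Hz are pulled ~1 Hz down (spectral
  tuning mass beyond 60 Hz is truncated). Interior resonances
  (35–54 Hz) are recovered exactly at high SNR and at a 95% rate at
  amplitude-to-noise 2 with 30 trials — the validation suite computes
  both. Empirical IGF distributions from this analysis should be read
  with that edge behavior in mind (pile-ups at the range floor are
  expected).
* At 200 Hz sampling the residual sub-Hz smoothing bias can round
  single-subject IGFs ±1 Hz even mid-range; recovery experiments
  therefore run at 250 Hz or above.
* Normalized ERSP curves inherit a mild upward tilt in frequency from
  dividing by the 1/f noise floor; IGF-recovery validation uses raw
  ERSP curves for that reason.
* Absolute raw ERSP units depend on the wavelet normalization
  (documented above) and are not comparable across toolboxes; compare
  baseline-normalized values only.
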