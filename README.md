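# efrchirp

Analysis of gamma-range auditory **envelope-following responses (EFR)** to
chirp-like click trains, in R.

Periodic auditory stimulation entrains EEG activity at the stimulation
rate. A chirp-like click train whose instantaneous rate sweeps 30 → 60 Hz
and back again probes the whole low-gamma range in a single stimulus, so
that per-frequency response strength, the **individual gamma frequency**
(IGF — the stimulation rate eliciting the strongest response), and
hemispheric lateralization can all be estimated from one recording. This
package implements the full analysis chain for such experiments, plus a
synthetic-EEG cohort generator so every stage can be validated against
ground truth. It is aimed at auditory/EEG researchers who want a tested,
scriptable replica of this analysis outside Matlab.

## What it computes

Given epoched EEG (trials × channels × samples) and the chirp timeline:

1. **Chirp frequency-to-time mapping** — each stimulation frequency f
   occupies one period 1/f; cumulative sums of 1/f give its time in the
   descending and ascending sweeps (total duration ≈ 1.44 s for 30–60 Hz
   in 1-Hz steps).
2. **Complex Morlet wavelet decomposition** (14 cycles, 30–60 Hz),
   trial-resolved: X_n(f, t).
3. **Phase-locking index** (inter-trial phase coherence)

       PLI(f, t) = (1/N) | Σ_{n=1}^{N} exp(i φ_n(f, t)) |,   φ_n = arg X_n

   and **event-related spectral perturbation**

       ERSP(f, t) = (1/N) Σ_{n=1}^{N} |X_n(f, t)|²,

   each divided by its mean over the −500…0 ms pre-stimulus baseline
   (relative baseline normalization).
4. **Response curves and IGF** — per stimulation frequency, values are
   averaged over a nine-channel fronto-central ROI (F1, Fz, F2, FC1, FCz,
   FC2, C1, Cz, C2) and over two 150-ms windows anchored at that
   frequency's time in each sweep (300 ms of data per frequency); the
   curve's argmax is the IGF.
5. **Laterality index** LI = (L − R)/(L + R) over the mirrored
   three-channel ROIs (F1, FC1, C1 vs F2, FC2, C2); negative = right
   dominance.
6. **Group statistics** — per-frequency Wilcoxon rank-sum tests with
   Bonferroni correction (m = 31), signed-rank tests for paired IGF
   comparisons, Spearman correlations of responses at IGF vs 40 Hz, and a
   chi-square test of independence for demographic proportions.

The simulator generates cohorts with controllable phase locking (von
Mises concentration κ), evoked amplitude, resonance frequency, Gaussian
frequency tuning, fronto-central topography and 1/f background noise; the
expected noise-free PLI is the Bessel ratio I₁(κ)/I₀(κ), which the test
suite verifies.

## Worked example

```r
library(efrchirp)

chirp_timeline(frequency_grid())
#> Chirp timeline: 31 frequencies 30-60 Hz, duration 1.4364 s

chi_square_independence(matrix(c(33, 9, 26, 12), 2, byrow = TRUE))
#> Chi-square independence: statistic = 1.062, p = 0.3028 (n1 = 42, n2 = 38)

# two-group study replica: 42 + 38 simulated subjects, female-like group
# with weaker/less phase-locked responses, same IGF distribution
report <- run_study(study_config(seed = 1))   # a few minutes
report
#> EFR study replica: 42 F + 38 M subjects, 100 trials @ 200 Hz
#>   PLI: significant band 30-48 Hz; IGF between-group p = 0.07
#>   ERSP: significant band 33-43 Hz; IGF between-group p = 0.112
#>   mean IGF_PLI (F) = 41.24 Hz, mean LI_PLI at IGF = +0.022
#>   mean IGF_PLI (M) = 38.21 Hz, mean LI_PLI at IGF = -0.017
write_report(report, "efr-report")
```

The replica shows the dissociation this analysis is designed to expose:
the stronger group produces a Bonferroni-significant band of PLI/ERSP
differences around 40 Hz, while IGFs (drawn from the same distribution in
both groups) and laterality indices (symmetric topography) do not differ.
`write_report()` emits per-subject tables, per-frequency comparison
tables and a JSON summary.

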