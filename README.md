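# concertsync

Multiscale movement-synchrony analysis for live-concert audiences.

When an ensemble performs the same piece twice — once strictly to the score
("Strict"), once in a deliberately improvisatory state of mind ("Let-go") —
do listeners move differently with the music and with the musicians?
`concertsync` answers this from body-worn accelerometer recordings. It is
written for researchers in music cognition and social physiology who have
per-subject triaxial acceleration, a performance design table, and
post-performance Likert ratings, and who want the full chain from raw
signals to mode contrasts and rating associations.

## What it computes

Raw axes are collapsed to the acceleration norm
`a(t) = sqrt(ax^2 + ay^2 + az^2)` and resampled to 50 Hz. Synchrony between
two listeners (or a performer and a listener) is the wavelet transform
coherence

    R^2(t, s) = |S(s^-1 W^X W^Y*)|^2 / ( S(s^-1 |W^X|^2) S(s^-1 |W^Y|^2) )

with a Morlet mother wavelet (omega0 = 6, 12 scales per octave, Fourier
periods 0.5-32 s) and smoothing `S` in time (Gaussian, SD = scale) and
scale (0.6-octave boxcar). Per-scale time means and temporal SDs are
aggregated per audience member over performers (P-A) or over the other
listeners (A-A). At each timescale the performance-mode contrast is fit
with a mixed model (`DV ~ Blindfold*Composition*Mode + (1|Subject) +
(1|Composition:Subject) + (1|Mode:Subject)`, deviation-coded, Satterthwaite
tests, exact paired fallback for degenerate fits) and Benjamini-Hochberg
corrected across scales. Timescales with significantly higher synchrony in
Strict form the **beat-sync** band, higher in Let-go the **music-sync**
band, and higher temporal SD in Let-go the **music-sync-variability** band;
band-averaged measures per subject and performance feed repeated-measures
correlations with the ratings (`r`, `t = r*sqrt(df/(1-r^2))`,
`df = N - subjects - 1`).

Breathing is reconstructed from the z-axis by wavelet inversion over 3-5 s
periods; pairwise phase-locking values come from analytic-signal phases and
the per-listener entropy rate from an AICc-selected autoregressive model
(`ER = 0.5*ln(2*pi*e*sigma_innovation^2)` nats per sample). An audio module
supplies a windowed loudness curve (dBFS, 200 frames/s, 480-sample window),
LZ76 loudness-pattern complexity, spectral entropy, and per-section bar
tempo variability from onset annotations. A seeded synthetic concert-cohort
generator plants all of these mechanisms with known ground truth and drives
the test suite.

## Worked example

```r
library(concertsync)

truth  <- synthetic_truth()                      # planted study conditions
config <- cohort_config(n_audience = 12, n_performers = 4,
                        duration_s = 130, fs = 50, seed = 1)
cohort <- gen_cohort(config, truth)

prof <- profiles_table(cohort$recordings, cohort$design,
                       channel = "pa", analysis_fs = 50)
ba <- band_analysis(prof, cohort$design, q = 0.05)
ba$bands
#> synchrony bands (P-A, q = 0.05):
#>   beat-sync periods:  0.5, 0.53, 0.561, 0.595, 0.63, 0.667, 0.707, 0.749, ...
#>   music-sync periods: ..., 6.35, 6.73, 7.13, 7.55, 8, 8.48, 8.98, 9.51, ...
#>   variability periods: 0.5, 0.53, 0.561, 0.595, 0.63, 0.667, 0.707, ...

head(ba$measures, 3)
#>   subject_id piece   mode beat_sync music_sync music_sync_var
#> 1        A01 Haydn Let-go     0.399      0.706          0.234
#> 2        A02 Haydn Let-go     0.505      0.475          0.224
#> 3        A03 Haydn Let-go     0.506      0.360          0.230
```

The beat-sync band covers sub-5-s periods around the planted 0.74 s beat
and its metrical neighbours, the music-sync band the planted 8-16 s gesture
scales. Averaged over this cohort the band measures shift exactly as
planted: beat-sync is 0.17 lower in Let-go than Strict, music-sync 0.17
higher, and music-sync variability 0.10 higher (the values
`scripts/acceptance.R` prints for seed 1). Breathing behaves the same way:

```r
breath <- cohort_breath_summary(cohort$recordings, cohort$design)
aggregate(cbind(mean_plv, entropy_rate) ~ mode, breath, mean)
#>     mode mean_plv entropy_rate
#> 1 Let-go    0.712        -2.23
#> 2 Strict    0.903        -2.31
```

Strict breathing locks more tightly to the shared driver (mean pairwise
PLV 0.90 vs 0.71) while the Let-go breathing pattern is more diverse
(higher entropy rate). Ratings generated from the cohort's planted
long-scale sync variability correlate with it within subject
(`rm_corr()`; the acceptance script reports r = 0.85 at this size).

## Layout

- `R/` — cohort generator, kinematics, wavelet coherence, band statistics,
  breathing, ratings, audio metrics, WAV/CSV IO
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent oracles
- `vignettes/concertsync-methods.Rmd` — models, assumptions, parameter
  choices, calibration caveats, limitations
- `inst/cli/concertsync.R` — thin command-line front end
  (`simulate`, `wtc`, `bands`, `breath`, `ratings`, `audio`)
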