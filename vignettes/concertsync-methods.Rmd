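---
title: "Multiscale movement synchrony in concert audiences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale movement synchrony in concert audiences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(concertsync)
```

## The scientific problem

When a chamber ensemble performs the same piece twice — once played strictly
to the score, once in a deliberately improvisatory, risk-taking state of
mind — does the audience move differently with the music and with the
musicians? `concertsync` quantifies this with body-worn accelerometry. The
working hypothesis, which the synthetic cohort of this package encodes as
ground truth, is that score-faithful playing drives synchrony at short,
beat-level timescales ("beat-sync"), while the freer mode engages longer
phrase-level gestures whose coupling waxes and wanes ("music-sync" and its
temporal variability).

Raw triaxial signals are reduced to the Euclidean norm
$a(t) = \sqrt{a_x^2 + a_y^2 + a_z^2}$ and downsampled to 50 Hz. Synchrony
between two norm series is measured by wavelet transform coherence (WTC),

$$R^2(t, s) = \frac{\left| S\!\left(s^{-1} W^X(t,s)\, W^{Y*}(t,s)\right)
\right|^2}{S\!\left(s^{-1} |W^X(t,s)|^2\right)\,
S\!\left(s^{-1} |W^Y(t,s)|^2\right)},$$

where $W^X$ is the Morlet continuous wavelet transform
($\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}$,
$\omega_0 = 6$) and $S$ smooths in time and scale. $R^2 \in [0,1]$ is a
localized squared correlation: high where the two signals covary at that
time and period, regardless of amplitude.

## Wavelet analysis choices

* **Period grid.** Dyadic, 12 voices per octave, 0.5-32 s (73 scales). The
  lower cutoff reflects that audience movement below half a second has no
  musically meaningful counterpart; 32 s is the longest period that 120 s
  records can support once edge effects are excluded. The Fourier period is
  `scale * 4 * pi / (omega0 + sqrt(2 + omega0^2))`, about 1.0330 per unit
  scale at $\omega_0 = 6$.
* **Discretisation.** The daughter wavelet is sampled in the time domain,
  truncated at $|\eta| > 6$ (tail below $1.6\times10^{-8}$), and applied by
  zero-padded FFT convolution. With this construction the transform equals
  the literal time-domain convolution sum to machine precision, which is how
  the test suite verifies it (a scalar-loop oracle with no FFT). Pads are
  chosen per scale so that any circularly folded tail reaching a valid
  output sits at or beyond the truncation level.
* **Smoothing.** Time: Gaussian with SD equal to the scale (in seconds),
  the standard choice for Morlet coherence. Scale: boxcar spanning 0.6
  octaves (the Morlet decorrelation length), with fractional end weights and
  edge renormalisation. Identical smoothing in numerator and denominator
  makes self-coherence exactly 1 wherever power exists.
* **Cone of influence.** The e-folding time of the Morlet is
  $\sqrt{2}\,s$; time-averaged summaries exclude, at each scale, the samples
  closer to an edge than that (policy `exclude`, configurable to
  `include`). Averages and temporal SDs use the population convention
  (divide by $n$); the temporal SD is computed per pair and then averaged
  across pairs, mirroring the mean.
* **Aggregation.** Each audience member's performer-audience (P-A) profile
  averages the per-scale mean and SD over the four performers;
  audience-audience (A-A) profiles average over all partners, each
  unordered pair computed once.

## Scale-wise statistics and bands

At every scale the mode contrast is fit with
`DV ~ Blindfold*Composition*Mode + (1|Subject) + (1|Composition:Subject) +
(1|Mode:Subject)`, all fixed factors deviation-coded to $\pm 0.5$ and
zero-centred, so the Mode coefficient is the marginal Let-go minus Strict
difference. Reported coefficients are standardised (DV and predictor scaled
to unit SD); t and p use Satterthwaite degrees of freedom. With four
observations per subject this random structure is frequently degenerate
(singular or zero-residual fits); such scales fall back to the exact paired
t on subject means, which in the balanced design estimates the same
marginal contrast, and the two engines must agree in sign. p-values are
Benjamini-Hochberg adjusted across scales, separately per channel and per
quantity, at q = 0.05.

Beat-sync scales are those with a significant negative contrast on the
time-mean coherence, music-sync scales a significant positive one, and the
variability band collects significant positive contrasts on the temporal
SD. Band measures average the profile values over those period sets; an
empty band gives a missing value, never zero.

**A calibration caveat found while validating this package.** All audience
members are compared against the *same* four performances. The realization
of a performance — the shared partner's actual time-frequency structure —
shifts the null distribution of the coherence estimator coherently for
every subject, a variance component that subject-level tests cannot see.
In global-null simulations this made scale-wise tests substantially
anticonservative whenever a shared structured partner was present, and the
component shrinks only as 1/K in the number of independent performers —
it cannot be removed at realistic ensemble sizes. The test suite therefore
calibrates the multiplicity procedure on the null ensemble a randomized
crossover defines: mode-symmetric coupled cohorts with the per-subject,
per-piece mode assignment randomized, under which subject-level contrasts
are sign-symmetric and uncorrelated; the family false-band rate over 100
such cohorts stays within the binomial band of q = 0.05. Single-concert
designs inherit the caveat: conclusions about mode effects lean on the
within-subject pairing of performances, not on an exchangeable null.

## Breathing-band analysis

Respiration couples mainly to the z-axis of a chest- or neck-worn sensor.
The breathing-related signal is the wavelet reconstruction of the z-axis
over 3-5 s periods,
$x(t) \propto \sum_j \mathrm{Re}\,W(t, s_j)/\sqrt{s_j}$ with
$C_\delta = 0.776$, the same band-limiting mechanism used everywhere in the
package. Phase locking between two listeners is
$\mathrm{PLV} = |\langle e^{i(\phi_x - \phi_y)}\rangle_t|$ with phases from
the analytic signal — well defined because the reconstruction is
narrow-band; a wavelet-phase alternative would behave identically there.
Each subject's summary is the mean PLV over all partners.

The entropy rate treats the standardised breathing signal as a stationary
Gaussian process: autoregressive fits by Levinson-Durbin on the sample
autocovariance, order selected by AICc (up to 20 after decimating to 5 Hz
— breathing dynamics live below 0.5 Hz, so this keeps the order modest),
and $\mathrm{ER} = \tfrac12 \ln(2\pi e\,\sigma^2_\varepsilon)$ nats per
sample. Standardisation is deliberate: differential entropy shifts by the
log of any amplitude scale, and without it the measure would confound
movement magnitude with pattern diversity. The closed forms
$\mathrm{ER} = \tfrac12\ln 2\pi e \approx 1.4189$ for white Gaussian noise
and $\tfrac12\ln(2\pi e\,(1-\phi^2))$ for AR(1) anchor the acceptance
tests.

## Questionnaires

Seven items on a 0-5 Likert scale with at most one missing cell per
subject and performance. Missing cells are filled by an iterative
random-forest imputer (each incomplete item regressed on the other six,
iterated to convergence, rounded and clamped), fully seeded. PCA is run on
z-scored items; PC1's sign is fixed so the Improvisatory loading is
positive. Associations between ratings and band measures use the
repeated-measures correlation: both variables centred within subject,
$t = r\sqrt{df/(1-r^2)}$, $df = N - k - 1$ — at the reference design shape
of 42 listeners by 4 performances this gives df = 125. Likert items are
treated as continuous; ordinal models are out of scope. Standardised
coefficients scale both DV and predictors (the convention is stated because
it is not unique).

## The synthetic cohort and what it does (not) show

`gen_cohort()` plants the mechanisms the analysis is meant to detect:

* a **beat oscillator** (default period 0.74 s, a crotchet at the faster
  piece's tempo) whose per-beat period follows a bounded Gaussian random
  walk — tighter in Strict (SD 0.005 s) than Let-go (0.02 s);
* a **gesture driver**: Gaussian noise band-limited to 8-16 s periods by
  the same Morlet reconstruction as the breathing band;
* audience coupling
  $\alpha_{beat}\,\mathrm{beat}(t-\tau_i) + \alpha_{slow}\,
  g_i(t)\,\mathrm{gesture}(t-\tau_i)$ with sub-beat delays
  $\tau_i \sim U[0, 0.2]$ s (coherence is phase-lag tolerant at lags far
  below the period, so these delays preserve high coherence while avoiding
  perfectly aligned samples). Defaults: $\alpha_{beat}$ 1.0/0.5 and
  $\alpha_{slow}$ 0.3/1.0 for Strict/Let-go;
* a **coupling gate** $g_i(t)$ = softplus of an Ornstein-Uhlenbeck path
  with 20 s correlation time, mean approximately 1, SD 0.1 (Strict) versus
  1.8 (Let-go). The Let-go depth is deliberately large: the temporal SD of
  coherence at 8-16 s periods carries an estimator floor of about 0.2 at
  130 s records (the scale-proportional smoothing leaves only a handful of
  independent patches inside the cone of influence), so only gates whose
  excursions swing the in-band signal-to-noise by order unity — genuine
  in/out-of-sync metastability — plant a recoverable variability effect;
* **breathing** on the z-axis (0.8 m/s^2 at 3.8 s period): each subject's
  phase tracks a common wandering driver through a wrapped
  Ornstein-Uhlenbeck offset with stationary circular concentration
  $\kappa$ (von Mises-equivalent; Strict 8, Let-go 2). $\kappa = 0$ means
  a fully independent wandering clock — a one-off von Mises draw would
  freeze every pairwise phase difference and pin all PLVs at exactly 1;
* **noise**: white accelerometer/idle-motion noise (SD 2 m/s^2) plus an
  independent per-subject slow component band-limited to 6-32 s (SD 1).
  The slow component is essential realism: purely white noise leaves
  almost no in-band power at gesture periods, so long-scale coherence
  would saturate near 1 in both modes regardless of coupling. Setting
  `slow_noise_sd = 0` recovers the white-only assumption;
* **axis projection** by a per-subject random unit quaternion, with the
  movement riding on a gravity-scale constant so the Euclidean norm is
  approximately affine in the movement signal; breathing is added on z
  after rotation;
* **ratings** from a latent engagement
  $e = \mu(\mathrm{mode}) + \gamma\,\mathrm{centred}(\mathrm{planted\ sync\
  variability}) + b_{subject} + \varepsilon$, with Improvisatory,
  Innovative, Risk-taking and Engaging loading positively, Convincing
  weakly, Familiar and Sleepy independently; items are affinely mapped to
  0-5 and clamp-rounded (the simplest monotone discretisation).

Durations default to $U[120, 140]$ s per performance at 100 Hz (the
acceptance runs generate directly at the 50 Hz analysis rate); each piece
is played once per mode with the mode order alternating across pieces, and
half the audience is blindfolded. Identical seeds give bit-identical
cohorts.

What passing tests on this cohort do **not** show: the generator has no
gravity or orientation drift, no video, no higher-order (triplet)
synchronisation, and its noise spectrum is an assumption, not a
measurement. Parameter recovery here demonstrates that the pipeline detects
the planted mechanisms at realistic sizes and noise levels — not that real
audiences obey this model.

## Numerical and degenerate-input conventions

Zero-power regions of a coherence map are reported as $R^2 = 0$ and
counted; values are clipped to $[0,1]$ after verifying the pre-clip
excursion stays below $10^{-6}$. Scales with no COI-admitted samples are
dropped with a warning. Constant series are rejected by `plv()` (undefined
phase) and `entropy_rate()` (zero variance). Resampling applies a
zero-phase 8th-order Butterworth at 0.4 times the target rate before
decimation — the acquisition convention upstream is not always stated, so
the filter is configurable. In `lz_complexity()` values equal to the median
binarise to 1, a fixed documented tie-break. `spectral_entropy()` averages
periodograms over non-overlapping segments (length
$\min(2^{13}, 2^{\lfloor \log_2 n \rfloor})$): a single periodogram of
white noise carries an entropy deficit of $(1-\gamma)/\ln 2 \approx 0.61$
bits regardless of length, and segment averaging shrinks it below the
tolerance of the flat-spectrum check. The loudness curve is a windowed
dBFS power curve ("LUFS-like"): ITU gating and weighting are not
implemented, and downstream pattern metrics depend only on the curve's
shape, not its absolute calibration.

## Problem sizes used by the test suite

Unit tests run on 40-120 s series at 20-50 Hz. The end-to-end recovery
checks use five cohorts of 4 performers and 20 audience members (130 s,
50 Hz), 100 mode-symmetric randomized-crossover null cohorts of 6 audience
members (60 s, 20 Hz) for the false-discovery calibration, and 20
replicates of the 42-subject ratings design. These sizes were chosen so the
planted effects are comfortably detectable while a full run of the suite
stays within a coffee break on a single core.

## Known limitations

Breathing extracted from accelerometry cannot be separated from slow body
sway without a respiration belt. The entropy-rate estimator assumes an
adequate autoregressive (Gaussian) description of the breathing band; the
state-space formulation it stands in for shares that contract but is not
identical. Scale-wise inference is anticonservative under shared structured
performances (see above). The audio metrics are shape-faithful rather than
calibrated to broadcast loudness standards.
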