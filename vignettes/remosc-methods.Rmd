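---
title: "Detecting and relating theta and beta oscillations in intracranial REM sleep recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and relating theta and beta oscillations in intracranial REM sleep recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remosc)
```

## The analysis problem

During REM sleep the human frontal cortex produces discrete bursts of
oscillatory activity in the theta (4–8 Hz) and beta (15–35 Hz) bands,
visible in depth-electrode recordings as band-limited power riding on an
aperiodic 1/f-type background. remosc implements the full chain needed to
characterise this activity from multichannel polysomnographic recordings:

1. **Staging** — find REM epochs from EMG, scalp EEG and EOG features and
   select long uninterrupted REM episodes for analysis.
2. **Oscillation detection** — decide, per bipolar derivation, whether a
   band carries power above the fitted aperiodic background.
3. **Burst detection** — extract discrete burst events from band-power
   envelopes.
4. **Coherence** — test whether two regions' signals are coherent in a
   band, with both an analytic null and a window-permutation null.
5. **Lead/lag** — measure which region's band-power envelope tends to
   lead, via the lagged cross-covariance of Hilbert envelopes.

Because clinical intracranial recordings cannot be redistributed, the
package ships a synthetic-data module (`gen_background()`,
`gen_burst_channel()`, `gen_coherent_pair()`, `gen_session()`) that
produces recordings with the statistical structure the analysis assumes —
and returns the ground truth, so that every stage is testable end to end.

## Data model and preprocessing

A `recording()` is a channels-by-samples matrix in microvolts with a
channel-metadata table (modality, region, shaft, contact index, gray
matter and exclusion flags). Native sampling rates are kept throughout
(500 Hz typically, 512 Hz supported); window lengths are always derived
from the rate rather than fixed sample counts, which avoids resampling
artifacts in the coherence estimates.

`make_bipolar()` forms one derivation per pair of adjacent contacts on a
shaft (consecutive contact indices), with the deeper (lower-index)
contact as the positive pole — a fixed sign convention so that results
are reproducible. With `region_restrict = TRUE` a derivation is kept only
when both contacts share a defined region and at least one lies in gray
matter, so band results can be attributed to a single region. Epileptiform
contacts are excluded through the metadata flag; the package deliberately
does not attempt automatic spike detection, since that exclusion is an
expert clinical judgement.

## Sleep staging

`epoch_features()` computes, per 30 s epoch: broadband EMG power
(10–100 Hz), scalp delta power (0.5–4 Hz), scalp spindle-band power
(11–16 Hz), and the sum over ±1 s lags of the demeaned EOG-pair
cross-covariance. The EOG montage places conjugate eye movements with
opposite polarity on the two leads, so rapid eye movements drive the
cross-covariance sum negative.

`classify_rem()` labels an epoch REM when EMG power is at or below the
0.2 quantile of the night, delta and spindle power at or below their 0.3
quantiles, and the EOG sum is negative. Quantile (rather than absolute)
thresholds are used because the defining criterion — "the lowest EMG of
the night" — is intrinsically relative; the three quantiles are tunable.
This classifier is a feature-threshold stand-in for full human-scored
AASM staging, not a re-implementation of it: it reproduces the features a
scorer uses, but none of the contextual rules. `select_rem_episodes()`
then keeps maximal runs of consecutive REM epochs strictly longer than
5 min, uninterrupted by any other stage, untrimmed (a 21 min episode
yields 126 ten-second analysis windows).

The classifier is monotone in its thresholds (raising a quantile never
removes a REM label), which the test suite checks as a property.

## Oscillation detection against a 1/f null

REM episodes are divided into non-overlapping 10 s windows. Each window
gets a multitaper power spectrum (Slepian tapers; time-halfbandwidth 4
with 7 tapers by default, i.e. 0.8 Hz resolution bandwidth). The tapers
are computed from the classical tridiagonal form of the spectral
concentration problem, with Sturm-sequence bisection plus inverse
iteration, and are validated in the tests against the defining
sinc-kernel eigenproblem.

Each window's spectrum is then fitted with the aperiodic model
$a f^b$ on 2–50 Hz (excluding a mains guard band) by iteratively
reweighted least squares on $\log S$ vs $\log f$ with bisquare weights
(tuning constant 4.685). Robust weighting makes band-limited peaks act as
outliers, so the fit tracks the background under them. Two numerical
choices matter here:

* **Log-domain fitting** linearises the model and makes the robust loss
  symmetric in orders of magnitude; the fit range and the line-noise
  exclusion are configurable.
* **Level rebalancing.** Spectral estimates are chi-square distributed
  around the true spectrum, and the geometric mean of a chi-square
  variate lies below its expectation, so a raw log-domain fit sits
  systematically below the spectrum even when no oscillation exists.
  With ~125 windows per electrode, a paired test would convert that
  offset into a grossly anticonservative detection rate. `fit_power_law()`
  therefore rescales $a$ by the ratio of spectrum to fit over the fitted
  band, averaged with the robust fit's final bisquare weights. Weighting
  matters: oscillatory peaks carry (near-)zero weight, so a channel's
  theta bump cannot inflate the background level and mask a genuine beta
  excess, while under a pure power-law null almost no bin is downweighted
  and the linear-scale residuals are centred at zero. The step is exactly
  neutral on noiseless power-law input.
  The acceptance suite verifies that with this step the band test's
  type-I error at $\alpha = 0.05$ sits inside the binomial interval over
  200 replicate null electrodes.

For each band the per-window band means of spectrum and fit form matched
pairs, compared by a paired two-sided t-test across windows (the pairing
reflects that each window contributes one spectrum and one fit).
Significance is Bonferroni-corrected by the number of electrodes tested
together, and the band peak frequency is the frequency of maximum mean
excess above the fit, reported only for significant electrodes.
`summarize_region()` aggregates electrodes into the fraction-significant
and median-peak-frequency summaries used for regional reporting.

## Burst detection

`band_envelope()` band-passes with a zero-phase FIR filter (Hamming
design; 1 Hz transition width for bands starting below 10 Hz, 2 Hz
otherwise) and takes the magnitude of the analytic signal. Burst power is
the squared envelope — one envelope definition is used consistently for
burst detection and for the lead/lag analysis. `detect_bursts()`
thresholds at the episode median plus 3 SD of power, keeps runs of at
least two cycles of the band centre frequency (80 ms for 25 Hz beta), and
merges runs separated by less than one cycle before the duration test so
that sub-cycle envelope dips do not split a burst. The median + SD
threshold mixes a robust centre with a non-robust spread; it is kept
deliberately, as the field's printed convention for this analysis.

A practical accuracy note, quantified in the tests: with cosine-ramped
burst envelopes the threshold crossing sits partway up the onset ramp, so
detected boundaries land within roughly a tenth of the burst duration
(tens of milliseconds) of the true support rather than exactly on it.
Event recovery is therefore asserted as interval overlap (Jaccard ≥ 0.5)
plus a boundary-error bound at the ramp-crossing scale, and the theta
recovery condition uses longer, stronger bursts than beta because the
narrow theta filter smears short envelope edges.

## Coherence with analytic and permutation nulls

All REM episodes of a session are divided into non-overlapping 2 s
windows pooled into a single magnitude-squared coherence estimate per
electrode pair, $|C(f)|^2 = |\sum S_{ab}|^2 / (\sum S_{aa}\sum S_{bb})$,
summing over every window–taper combination. The taper half-bandwidth is
set to half the band width so the estimate read at the band centre
integrates the entire band (theta: time-bandwidth 4, 7 tapers; beta:
time-bandwidth 20, 39 tapers), and the coherence is read at the single
grid frequency nearest the centre rather than averaged across bins.

Under zero true coherence the pooled estimate with $m$ = windows ×
tapers degrees of freedom follows a Beta(1, m−1) law; the normalised
density is $(m-1)(1-x)^{m-2}$, giving the upper-tail probability
$p = (1-|C|^2)^{m-1}$ and the threshold $1-\alpha^{1/(m-1)}$. The
permutation null (`mc_pvalue()`, 2000 shuffles by default) permutes the
order of one channel's windows — destroying the pairing while preserving
both marginal spectra — and uses the add-one p-value rule. A pair is
declared significant only when **both** p-values clear the
Bonferroni-corrected level, so the two null constructions must agree.
The acceptance suite verifies the Beta null distribution on independent
channels at $m = 700$, the empirical type-I error of the analytic
threshold, and a rank correlation above 0.9 between the two p-values
across null datasets.

## Envelope lead/lag

For pairs with significant band coherence, the per-window cross-covariance
of the two Hilbert envelopes is computed over the 2 s windows in which
both electrodes' band power reaches its top quartile (per episode), then
averaged within pair and across pairs. The sign convention — pinned by a
dedicated test — is that a peak at positive lag means the first-argument
(DLPFC) envelope leads. The reported quantities are the lag of the
grand-average maximum (ties broken toward zero) and the ±100 ms asymmetry
index, the difference between the areas under the function on (0, +100]
and [−100, 0) ms by the trapezoidal rule.

Two estimator details are deliberate:

* `window_crosscov()` is the plain within-window estimator with biased
  1/N normalisation and per-window demeaning (which removes slow power
  drift); its exchange antisymmetry
  $CC_{d,a}(\tau) = CC_{a,d}(-\tau)$ is exact and tested.
* For lag *estimation*, `pair_crosscov()` by default reads the lagged
  channel from the episode envelope continuing past the window edges.
  The within-window estimator's truncation multiplies the expected
  function by the triangular factor $1-|\tau|/N$, which pulls the apex
  of broad envelope cross-covariances toward zero lag by tens of
  milliseconds; reading past the edges removes the distortion entirely
  (a pure envelope shift is then recovered exactly). Windows whose lag
  extension would leave the episode are skipped.

Lag-recovery accuracy depends on the envelope bandwidth: beta-band
envelopes (up to 10 Hz of envelope bandwidth) localise the apex to within
a sample or two, while theta envelopes are intrinsically smooth (≤ 4 Hz),
so the calibrated lag-recovery guarantee (±2 samples over a 20-seed
cohort at mixing 0.8, true lags 0–50 ms) is asserted on beta-band pairs;
theta recovery is demonstrated at its coarser intrinsic resolution.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture:

* `gen_background()` shapes white noise in the frequency domain so the
  expected one-sided spectrum equals $a f^b$ from 1 Hz to Nyquist (flat
  below 1 Hz to keep variance finite). Frequency-domain shaping, rather
  than an AR approximation, gives exact control of the target the robust
  fit must recover.
* Bursts are sinusoids at the band centre under a cosine-tapered (Tukey)
  amplitude window with raised-cosine ramps over half the duration. The
  full window support defines the true burst duration in cycles; the
  flat top keeps the envelope-threshold crossing close to the true
  boundaries, which a full raised-cosine bell would not.
* Burst *SNR* is defined as peak envelope power relative to the
  background's mean band-envelope power ($A^2 = 2\,\mathrm{snr}\,
  \sigma^2_\mathrm{band}$).
* `gen_coherent_pair()` couples two channels through a shared, delayed
  burst source (channel B = mixing × delayed source + (1−mixing) ×
  private source + private background). A delayed shared source — rather
  than phase-coupled oscillators — directly realises a known envelope
  lag, which is exactly the quantity the lead/lag analysis estimates.
  Integer-sample delays keep the truth on the lag grid.
* `gen_session()` scripts a whole night. The default scenario is a
  compact 60 min night (REM fraction 17.5%, a single 10.5 min REM
  block), with stagewise EMG noise giving at least four-fold variance
  atonia in REM, a scalp channel that is low-voltage in REM, carries
  alpha in wake, delta in N2/N3 and spindle bursts in N2, and an EOG
  pair with conjugate opposite-polarity monophasic deflections during
  REM (saccadic shifts of the corneoretinal potential have non-zero
  integral, which is what makes the lag-summed EOG cross-covariance
  reliably negative). The REM fraction is kept below the EMG quantile
  threshold so that the relative "lowest of the night" criterion can
  cover every true REM epoch.

What the generator does *not* emulate: non-stationary background drift,
inter-subject montage variability, arousals and stage transitions,
epileptiform transients, volume conduction, or any biophysically
realistic circuit dynamics. Passing tests therefore demonstrate that the
estimators are calibrated and recover their own model's structure — not
that real recordings satisfy that model.

## Problem sizes and reproducibility

The calibration and recovery checks run at deliberate desk scales: 200
replicate null electrodes of 125 windows for the band-test calibration,
200 independent pairs at m = 700 for the coherence null, 50 null
datasets for the analytic-vs-permutation comparison, 20-seed cohorts of
240 s pairs for lag recovery, and 10 sessions of the 60 min default
scenario for staging. Every generator call is a pure function of its
seed, the pipeline derives per-stage child seeds from one master seed,
and result CSVs are written at 6 significant digits so repeated runs are
byte-identical.

## Worked example

```{r example, eval = FALSE}
library(remosc)

sess <- gen_session(scenario_spec(seed = 1))
feats <- epoch_features(sess$recording)
hyp <- classify_rem(feats)
episodes <- select_rem_episodes(hyp)

win10 <- window_rem(episodes)
tests <- test_band_power(channel_signal(sess$recording, "dDLPFC1"),
                         sess$recording$sample_rate, win10,
                         bands = c("theta", "beta"), electrode_id = "dDLPFC1")
tests

cfg <- pipeline_config(scenario = scenario_spec(seed = 1), seed = 1)
res <- run_pipeline(cfg)
write_report(res)
```

## Known limitations

* The staging classifier needs at least 20 epochs and a night whose REM
  fraction lies below the EMG quantile threshold; it has no notion of
  N1–N3 substages or arousals.
* The burst threshold statistics (median, SD) are computed per episode;
  nights with strongly non-stationary background would need an external
  normalisation.
* The analytic coherence null assumes window–taper products are
  independent draws, which non-overlapping windows and orthogonal tapers
  approximate but heavily overlapped spectra would not.
* Theta-band lag estimates are limited by the envelope's intrinsic
  smoothness; sub-10 ms theta timing claims are outside what the
  estimator can resolve at realistic SNR.
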