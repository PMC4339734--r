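---
title: "Breathing-sound analysis of sleep and wake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-sound analysis of sleep and wake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightbreath)
```

## The estimation problem

A single non-contact microphone records a whole night. The task is to label
every 30-second epoch as sleep or wake and to summarize the night with the
standard sleep-quality parameters. The physiological premise is that
sleep raises upper-airway resistance: breathing during sleep is louder,
more periodic, and prone to snoring, while wakeful breathing is quieter and
irregular and is interspersed with movement noise. Every stage of the
pipeline is a measurement of one of those contrasts.

The pipeline is: noise suppression, acoustic-event scoring,
periodicity features, a boosted sleep-wake likelihood (SWL) score, a
per-subject decision threshold, and sleep-quality parameterization. This
vignette records the models, the tunable parameters, and the design
decisions made where the method description left choices open.

## Noise suppression

`spectral_subtract()` removes spectrally stationary background (fans, air
conditioning) with a Wiener-type gain per 60-ms Hann frame (50% overlap,
overlap-add reconstruction; output length and rate equal the input's).

The background power spectrum is tracked adaptively, with no voice/breath
detector in the loop: for each frequency bin the tracker takes a low
quantile (default the 10th percentile) of the short-time power over a
sliding 30-s window, updated every 5 s. Breathing events occupy well under
half of any 30-s window, so the low quantile sees between-breath background
even in dense breathing; the estimate is rescaled by the exponential-tail
factor $-1/\log(1-q)$, since the short-time power of stationary noise in a
bin is approximately exponentially distributed. Two consequences are worth
stating plainly:

* a *sustained constant tone* is, by this definition, background, and will
  be attenuated — which is the desired behavior for mains hum and machine
  tones;
* the tracker needs about one window (30 s) to settle; the first 5 s are
  bootstrapped from their own statistics.

The gain is $G = \max\!\big(1 - \alpha\,\hat\lambda / |X|^2,\;
G_{\min}\big)$ with oversubtraction $\alpha = 2.5$ and floor
$G_{\min} = 0.05$ (−26 dB). The floor suppresses musical noise and sign
flips; $\alpha$ was set from the closed form
$E[(s-\alpha)^+] = e^{-\alpha}$ for exponential normalized power $s$, which
gives ≈ 11 dB expected suppression of pure stationary noise, comfortably
inside the stage's ≥ 10 dB contract. The noise-history ring keeps every
second frame of the window: 50%-overlapped neighbors are nearly redundant
for a quantile, and this halves tracker cost at no practical loss.

## Events and snore likelihood

`detect_events()` is a deliberately simple surrogate for a full
breathing-sound detector, kept behind a pluggable interface (any external
event list can be supplied as CSV): events are maximal runs of envelope
frames more than 6 dB above a rolling 10th-percentile noise floor, with
runs closer than 100 ms merged and runs shorter than 200 ms dropped —
breath sounds last upwards of 0.2 s and intra-breath pauses are short.

`score_sls()` assigns each event a snore-likelihood score,
$$\mathrm{SLS} = w_h \cdot \text{harmonicity} + w_\ell\,(\text{peak} -
\text{floor})_{\mathrm{dB}} - c,$$
with $w_h = 4$, $w_\ell = 0.05$ per dB, $c = 2.5$. Harmonicity is the
maximum normalized autocorrelation of the low-passed (1 kHz) waveform over
candidate fundamental periods (60–200 Hz); it approaches 1 for a harmonic
snore and stays near 0 for band-limited breath noise. Level enters only
relative to the noise floor, so the score is invariant to global gain — a
recording-distance and body-posture robustness requirement. The constants
were calibrated once against the simulator's labeled snores and breaths so
that the sign convention (snore > 0) separates the classes; they are stored
with the model file.

## Breathing-periodicity features

For each non-overlapping 12-s and 24-s interval the magnitude spectrogram
$X_i(k,n)$ is computed from 60-ms Hann frames with 30-ms hop, band-limited
to 0–3 kHz, where breathing-sound energy lives. Each frequency band is then
autocorrelated,
$$R_i(k,t) = \frac{1}{N-t}\sum_{n=1}^{N-t} X_i(k,n)\,X_i(k,n+t),$$
after mean removal per band. Mean removal plus zero-lag normalization puts
all bands on a common scale, which the next step requires: bands are ranked
by the amplitude of their first positive autocorrelation peak within the
breathing-lag band, and the top 50% — the most periodic half — are averaged
into the emphasized autocorrelation $R_i(t)$, renormalized to
$R_i(0) = 1$.

Three features are read off $R_i(t)$:

* **Cycle period (CP)** — the lag of the first positive local maximum
  (zero lag excluded), refined by three-point parabolic interpolation so
  the estimate is not quantized to the 30-ms lag grid. Peak search is
  restricted to lags of 1.5–10 s (4–40 breaths/min); a 12-s interval must
  contain at least two breathing cycles, which motivates both the interval
  length and the band.
* **Cycle intensity (CI)** — the amplitude of that peak, clamped to
  $[0, 1]$ (the unbiased $1/(N-t)$ scaling can push normalized values
  fractionally above 1).
* **Cycle consistency (CC)** — the standard deviation of successive
  differences of all positive-peak lags in the band: 0 for perfectly
  regular breathing, growing with irregularity. The exact functional form
  of this feature was not fully specified in the method description; this
  reconstruction follows the stated operators (peak finding and standard
  deviation) and the stated behavior (more repetitive ⇒ lower value).

Features computed on the 12-s and 24-s interval grids are linearly
interpolated at epoch centers (15 s, 45 s, …) onto the 30-s grid; intervals
where no peak exists are flagged invalid and bridged by interpolation from
valid neighbors. Two per-epoch snore features complete the set of eight:
MaxSLS (maximum event SLS in the epoch; −3 sentinel for empty epochs,
below any calibrated score) and the snore index SI (positive-SLS events in
the epoch × 120, i.e. events/hour). Events are assigned to epochs by their
midpoints, so per-epoch counts partition the night's events.

Interval choices that were left open and decided here: intervals are
non-overlapping and timestamped at their centers; ties in peak location
resolve toward the smaller lag; a plateau counts as a peak at its first
sample.

## Classifier and threshold

Each epoch's 8 features are concatenated with those of the two previous
epochs (d = 24 columns; the first rows replicate the earliest epoch), and a
discrete AdaBoost classifier with depth-1 decision stumps is trained for up
to k = 100 rounds on the pooled design subjects. Sleep is −1, wake +1.
Stump thresholds sit at midpoints between consecutive distinct sorted
values; ties break toward the lowest column, then the lowest threshold, so
training is deterministic. A round with weighted error ≥ 0.5 stops
training without being added; a perfect round has its weight capped at the
ε = 10⁻⁸ value and stops training. The SWL score is the vote normalized by
the total round weight, $\sum_m \alpha_m h_m(x) / \sum_m \alpha_m \in
[-1, 1]$.

Per-subject adaptation happens only at decision time. The night's SWL
distribution is assumed bimodal (sleep and wake modes) and cut by Otsu's
method — here the exact minimizer of within-class variance over all
midpoints between consecutive distinct scores, with ties toward the lower
cut (a classical 256-bin histogram variant is available for comparison;
when the modes are separated by a score gap the objective is flat across
the gap, so the two variants can legitimately return different cuts of
equal quality). The per-epoch threshold adds a decaying early-night
offset,
$$L_{TH}(t) = L_{TH} + \max(0.5 - t/360,\ 0),$$
with $t$ the 0-based epoch index, so the offset vanishes at epoch 180 —
exactly 90 minutes. An epoch is sleep iff its score is strictly below the
threshold (a tied score is wake). Under this rule the raised early
threshold makes the sleep decision *more permissive* during the sleep
latency period, which protects the sleep-onset estimate; the offset can
advance the first sleep-labeled epoch but never delay it. Degenerate
nights whose SWL curve has fewer than two distinct values fall back to the
global cut at 0 with a warning.

## Sleep-quality parameters

From the binary hypnogram (0.5 min per epoch): SL is recording start to the
first sleep epoch (no N-consecutive-epochs onset rule); TST is the sleep
epoch count; SE = 100·TST/TIB; WASO counts wake strictly between the first
and last sleep epoch; AwI counts the distinct wake runs in that same span
per hour of TIB. The terminal wake run, after the final awakening, is
excluded from WASO and the awakening count by default (configurable), so
SL + TST + WASO + terminal wake = TIB is an exact identity.

## Evaluation suite

Sleep is the positive class. Per-subject and pooled-epoch
sensitivity/specificity/PPV/NPV/accuracy and Cohen's kappa are both
reported; ratios with empty denominators are returned as `NA` and excluded
from subject averages. ROC curves sweep a global additive offset applied
to each subject's threshold profile — mirroring how the deployed rule
actually operates — and the trapezoidal AUC equals the rank
(Mann–Whitney) concordance of threshold-relative scores, which the tests
assert. Bland–Altman limits are mean ± 1.96 sd of the per-subject
differences (audio-based minus reference). Audio-to-reference alignment
maximizes normalized cross-correlation on a 15-ms grid.

## The synthetic-night simulator

The simulator is the package's test bed and defines the conditions under
which the pipeline's claims are checked. A two-state Markov chain over
30-s epochs (self-transition 0.95 sleep / 0.85 wake, ≈ 25% wake long-run;
the chain starts awake so sleep latency is geometric) drives audio
synthesis: breaths every 4.0 ± 0.15 s in sleep and 3.5 ± 1.2 s in wake,
each a 0.8-s raised-cosine envelope (0.4-s inhale rise) of 300–3000 Hz
band-limited noise at −20 dBFS, 6 dB quieter in wake. Sleep breaths become
snores with probability 0.3, adding a 6-partial harmonic stack (1/k
amplitude decay) at a fundamental drawn from 80–150 Hz — the low-frequency
harmonic structure the SLS surrogate keys on. Wake epochs add 0.5-s
broadband movement bursts at 2 per wake-minute. Stationary white
background noise is mixed so breath peaks sit `background_snr_db` (default
20 dB) above it. Everything is a pure function of the configuration and
seed; audio is bit-reproducible.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about clinical recordings: apnea and hypopnea events,
REM/NREM acoustic differences, position changes and bed-partner sounds,
non-stationary interference (traffic, speech), room reverberation, and the
between-subject variability of real breathing acoustics. Results on
synthetic nights bound the pipeline's correctness, not its clinical
accuracy.

`simulate_features()` additionally draws the 8 features directly from
state-conditional normals (unit within-class sd, class means separated by a
configurable multiple in the empirically observed directions: sleep has
higher CI/MaxSLS/SI, lower CC), which isolates the classifier stack from
the audio stack in tests.

## Numerical and performance choices

* Spectral subtraction and the feature spectrogram share one short-time
  analysis: the enhanced magnitudes from the subtraction pass feed the
  periodicity features directly, avoiding a second transform pass over the
  night. Frame pairs share single complex FFTs in both directions
  (Hermitian packing).
* The per-band autocorrelation is evaluated through zero-padded FFTs with
  row pairs packed into single complex transforms (tiny inputs use direct
  summation in compiled code); both routes match the defining sum to
  machine precision, and the tests compare the production path against a
  triple-loop oracle at 10⁻⁹.
* Whole-night vectors are large (a 2-h night is 115M samples); the
  simulator adds background noise in chunks and the pipeline keeps a
  single whole-night copy live at a time, so multi-night studies stream
  subjects from disk.
* Checked problem sizes: the oracle equivalences run on 16×64
  spectrograms (20 seeds) and 200-score Otsu samples (50 seeds);
  cycle-period recovery uses 40 seeded 24-s intervals (the 12-s stream
  carries ≈ 2–3 breath gaps, whose sampling jitter alone spreads the
  realized period by ≈ 0.1 s, so the longer stream is the right one for a
  ±0.2 s check); classifier recovery uses 12 + 6 subjects × 240 epochs at
  feature level; the end-to-end study uses 12 design + 6 validation
  synthetic nights of 2 h at 20 dB SNR under the default configuration.

## Known limitations

* The event detector and SLS scorer are calibrated surrogates; real
  deployments should inject a validated external event list where
  available.
* The classifier is trained on pooled epochs; there is no per-subject
  feature normalization beyond the decision threshold.
* The binary design cannot stage sleep (REM/NREM), and the sleep-onset
  rule (first sleep epoch) is more liberal than scoring conventions that
  require consecutive epochs.
* Otsu's threshold assumes a bimodal night; heavily truncated recordings
  (all-sleep or all-wake) fall back to the global cut.
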