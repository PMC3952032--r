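---
title: "Decoding finger-tapping kinematics from delta-band EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger-tapping kinematics from delta-band EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tapdecode)
```

# The problem

Slow (delta-band, roughly 0.1--3 Hz) fluctuations of scalp EEG amplitude
carry information about continuously executed limb movements. `tapdecode`
implements a complete analysis for a self-paced finger-tapping task:
a subject taps the right index finger three times per trial while a data
glove records the metacarpophalangeal (MCP) joint angle and a 65-sensor
net records EEG. The package reconstructs the joint *angular velocity*
from the EEG, selects informative sensors with a genetic algorithm (GA)
inside a nested cross-validation, and quantifies movement-locked spectral
changes (alpha desynchronization, beta rebound) and per-lag correlation
topographies.

Because no public recording of this kind ships with the package, a
first-class synthetic-session generator produces EEG + glove data with
the statistical structure the analysis assumes — and with known ground
truth, so every stage of the pipeline can be validated quantitatively.

# The decoder

The core model is a lag-embedded (Wiener-style) linear decoder. With
$S'_i(t)$ the derivative of the preprocessed EEG of sensor $i$ and
$\theta'(t)$ the joint angular velocity,

$$\theta'(t) = \sum_{i=1}^{N}\sum_{k=1}^{L} b_{ik}\, S'_i(t - \tau_k),$$

with $N = 47$ usable sensors, $L = 7$ lags on the grid
$\tau_k = 0, 50, \dots, 300$ ms (past EEG only), and weights $b_{ik}$
fitted by ordinary least squares (a Gaussian GLM with identity link). An
intercept is included; it is harmless under standardization and required
for baseline-shifted inputs. Predictions are z-scored and smoothed with
the same 3 Hz low-pass used in preprocessing; decoding accuracy is the
Pearson correlation $r$ between the concatenated predicted and observed
velocities of the held-out trials of a fold — not an average of
per-trial correlations.

## Conditioning chain

Both modalities are brought to a common 100 Hz timeline:

1. EEG (500 Hz): Chebyshev II antialiasing low-pass (order 8, 60 dB
   stopband attenuation, stopband edge 40 Hz), downsample to 100 Hz.
2. Glove (non-uniform 35--70 Hz, 0.93° quantization): shape-preserving
   PCHIP interpolation onto the 100 Hz grid.
3. Reject the 18 peripheral rim sensors (frontal/temporal sites most
   affected by ocular and muscular artifacts), leaving 47 channels;
   common average reference.
4. High-pass 0.1 Hz (8th-order Butterworth), low-pass 3 Hz (1st-order
   Butterworth), both zero-phase; then the first-difference derivative
   (aligned by repeating the first sample).
5. Cut movement segments from 0.1 s before detected onset to 0.1 s after
   offset (half-open windows), baseline-correct each kinematic segment
   by its mean over $[-0.1, 0)$ s, concatenate, and z-score each EEG
   channel.

Two ambiguities were resolved as design choices. *Standardization*:
"standardized with respect to the means" is read as a full z-score
(center and scale); the statistics are computed on training trials only
and reused on held-out data, so no test information leaks into scaling.
*Lag context*: the lagged predictors at a segment's first samples are
taken from the continuous recording preceding the segment rather than
zero-padded, avoiding edge bias.

## Zero-phase filtering

All filters are applied with zero net phase. Rather than running the
recursion forwards and backwards (the textbook `filtfilt`), the package
multiplies the reflection-padded series in the frequency domain by the
filter's squared magnitude response $|H(f)|^2$ — the exact transfer
function of an ideal forward--backward pass. The reason is numerical:
the transfer-function coefficients of an 8th-order Butterworth high-pass
at 0.1 Hz on a 100 Hz series place all poles within $10^{-3}$ of the
unit circle, and both the recursion and the coefficients themselves are
numerically unusable (gain errors of an order of magnitude in the
passband). The warped-frequency magnitude responses of bilinear-
transformed Butterworth and Chebyshev II designs have closed forms that
are exact at any order, so that is what is evaluated. Edges use
odd-reflection padding of at least $3(\text{order}+1)$ samples, widened
to about three periods of the cutoff for narrow filters; high-pass
inputs are demeaned first, so a constant series maps exactly to zero.

Consequences worth knowing: linearity and time-reversal symmetry hold to
machine precision, and filter-response oracles in the tests are
evaluated against the warped (digital) response — e.g. a 1 Hz sinusoid
through the 3 Hz low-pass retains amplitude
$1/(1 + (\tan(\pi/100)/\tan(3\pi/100))^2) \approx 0.9006$, not the
analog $0.9000$.

One structural fact is worth knowing: after common average referencing
the 47 channels sum to zero at every sample, so the *full* lagged design
(all 47 channels at every lag) is exactly rank-deficient — one dependent
column per lag. `fit_decoder()` falls back to the minimum-norm solution
in that case (with a warning), and the GA's channel subsets are almost
always proper subsets, for which the design is full rank.

# Trial detection and kinematic statistics

Movement onset is the first sample in a trial window whose angular speed
(absolute first-difference of the angle) exceeds 5% of the window's
maximum speed; offset is the last such sample. The threshold is
relative, so bounds are invariant to offset and positive gain. Per-trial
statistics are: trial length, tapping speed ($3/\text{length}$), rest
position (mean over the 1 s windows before onset and after offset),
extension (mean of the three largest local maxima, prominence at least
10% of the trace range to suppress quantization jitter), and range of
motion. Statistics are computed on the raw upsampled angle, not the
3 Hz-filtered trace: the low-pass attenuates the tap peaks by about 20%
and would bias the extension estimate. Trial windows in unannotated data
come from a coarse 0.5 s moving-average energy scan (the task is
self-paced, so no cue markers exist); synthetic sessions carry true
windows.

The kinematic power spectrum uses the Thomson multitaper estimator with
time-bandwidth product 4 (hence $2\cdot4-1 = 7$ Slepian tapers) and
transform length 512. Slepian tapers are computed from the standard
symmetric tridiagonal eigenproblem. For series longer than 512 samples
the eigenspectra are averaged over non-overlapping 512-sample blocks —
a deliberate definition, since a "window length" shorter than the series
is otherwise ambiguous; shorter series are zero-padded. The 95%
cumulative-power frequency of the tapping trajectories stays below 3 Hz,
which is what justifies the 3 Hz low-pass.

# Nested cross-validation and the GA

The outer loop is 10-fold cross-validation over 100 trials in contiguous
blocks of 10 (fold membership can be shuffled behind a flag; the default
is sequential, as nothing suggests randomized assignment). Within each
outer fold, the GA searches channel subsets; an individual's fitness is
the median $r$ over an 8-fold inner cross-validation of the 90 training
trials (contiguous blocks of 11--12). The selected mask is then refitted
on all training trials and evaluated once on the held-out fold. No
held-out data reaches standardization statistics, GA fitness, or the
fit.

GA configuration: bit-string population of 20, uniform creation (bit
probability 0.5, all-zero individuals resampled), rank fitness scaling
(expectation $\propto 1/\sqrt{\text{rank}}$), stochastic universal
sampling, 2 elites, scattered crossover filling half of the non-elite
slots, uniform mutation (rate 0.01) for the rest, at most 100
generations. The stall rule stops the run when the weighted average of
the best-fitness improvements over the previous 30 generations — weights
halving per generation into the past — falls strictly below 0.01, once a
full window exists. Fitness evaluations are memoized (the fitness is
deterministic given the fold split), which makes converged populations
cheap.

For speed, each outer fold embeds the full $47 \times 7$ design once and
stores per-trial Gram matrices; a mask's fitness then reduces to solving
the masked normal equations of each inner fold, so a full GA run costs
seconds rather than hours.

# The synthetic generator

A session is the sum of, per channel:

* **Background**: Gaussian processes with a $1/f$ amplitude spectrum
  (flat below 0.1 Hz), optionally mixed across channels by a
  row-normalized Gaussian kernel on the montage coordinates
  (`spatial_sigma`, default 0.12 in head-radius units) and rescaled to
  unit variance. Amplitudes are arbitrary units throughout — the
  pipeline standardizes both modalities, so no microvolt scale is
  assumed.
* **Planted coupling**: on a small set of central channels (default 3,
  left-central, chosen well-separated), a copy of the 3 Hz-low-passed
  joint-angle trajectory shifted *forward* in time by that channel's lag
  (50--150 ms by default). Because the pipeline differentiates the EEG,
  the channel's feature becomes the lagged joint velocity: the decoder's
  model class holds exactly, with one informative lag per channel.
* **Alpha/beta modulation**: 10 Hz oscillations on twelve bilateral
  central channels whose amplitude is halved during movement
  (emulating movement-related alpha desynchronization) and 25 Hz
  oscillations whose amplitude doubles for 1 s after movement offset
  (beta rebound), with 0.1 s envelope ramps.
* **Artifacts**: slow drift and blink-like Gaussian transients confined
  to the 18 peripheral rim channels; optionally a movement-locked
  component (the normalized tap waveform) at amplitude
  `artifact_kin_coupling`, emulating task-correlated facial/ocular
  activity that makes peripheral-only decoding informative.

The glove trace is the true trajectory sampled at non-uniform intervals
drawn uniformly from $[1/70, 1/35]$ s and quantized to 0.93°. Tap
trajectories are raised-cosine flexion--extension pulses (three per
trial), which keeps 95% of the spectral power below 3 Hz at
physiological tapping rates. Default behavioral parameters emulate
pooled statistics of such a task: rest $-18.6^\circ$, extension
$+18.6^\circ$ (aligned to the glove quantum so the resting trace
quantizes without bias), trial length $1.84 \pm 0.48$ s truncated at
0.5 s, and self-paced inter-trial rests averaging 4 s with a 2.5 s
floor (so every trial has room for the rest-window analyses). A single
seed drives every stochastic component.

## SNR calibration and the correlation ceiling

The coupling strength is specified as a feature-domain signal-to-noise
ratio: the planted copies are scaled so that, after the full
deterministic conditioning chain, the summed ratio of coupled-component
variance to background variance over movement segments equals `snr`.
With independent channel noise, the best linear read-out of the true
design then has population correlation

$$r_{\max} = \sqrt{\frac{\mathrm{snr}}{1 + \mathrm{snr}}},$$

which is stored in the ground truth as `r_ceiling`. Two caveats are
deliberate and documented:

* The ceiling applies to the *true design* — each planted channel at its
  single planted lag — and to the *raw* OLS prediction.
  `decode_true_design()` measures exactly that. The full 7-lag grid can
  legitimately exceed the ceiling by whitening the temporally correlated
  $1/f$ background, and the postprocessing low-pass removes out-of-band
  prediction noise; both are features of the method, not bugs of the
  calibration.
* Common average referencing leaks about $1/47$ of the planted signal
  into every other channel and slightly perturbs per-channel variances;
  the measured ceiling deviation from this is below 0.05 in $r$.

## What the generator does not emulate

No volume conduction / forward head model (spatial structure is a
smoothing kernel), no non-stationarity of the background, no EMG, no
real ocular waveforms, and only one kinematic joint. Passing tests
therefore demonstrate correctness of the *analysis* under its own model
assumptions — not that real EEG supports any particular accuracy.

# Validation experiments and their design

* **Null decode (rest EEG)**: features are taken from rest windows of
  movement-segment length ending 0.1 s before each onset, while the
  target remains the movement-period velocity; with no rest-period
  coupling the outer-CV median $r$ is statistically indistinguishable
  from 0. The planted (leading) coupling extends at most 0.3 s before
  movement, so rest windows are essentially coupling-free.
* **Channel recovery**: the GA recovery experiment runs one GA per
  independently generated session (spatially independent backgrounds,
  snr 0.5) and pools best masks across runs. Two subtleties dictate this
  design. First, with spatially mixed noise, neighbours of coupled
  channels share background noise and are genuinely informative (noise
  cancellation), so "decoy" would be ill-defined. Second, the 10 outer
  folds of a *single* session share 80% of their training trials:
  channels whose noise happens to correlate with the kinematics of that
  session are consistently selected across folds, so fold-wise masks are
  not independent draws and the binomial chance model (inclusion
  probability 0.5) does not hold for them. Across independent sessions
  the model applies, planted channels are selected in every run, and
  decoys fall well below the 8-of-10 threshold. The within-session
  fold histogram remains what a real analysis reports — there, the
  binomial threshold is a descriptive flag, not a calibrated test.
* **Spectral calibration**: halving the alpha amplitude during movement
  yields a relative power change of $0.5^2 - 1 = -0.75$; the measured
  per-channel median alpha ERD lands within 0.1 of it (residual
  broadband background in the 8--13 Hz band biases it slightly towards
  zero). Under a null session (no modulation) the rest and movement
  windows are exchangeable, so the sign test is exactly calibrated and
  its per-channel significance rate at $\alpha = 0.05$ is 5%.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lags_ms` | 0--300 by 50 | decoder memory (ms; past EEG only) |
| `highpass` | 0.1 Hz, order 8 | drift removal |
| `lowpass` | 3 Hz, order 1 | delta-band isolation |
| `antialias` | 40 Hz, order 8, 60 dB | stopband edge before decimation |
| `onset threshold` | 5% of max speed | trial bound detection |
| `segment margin` | 0.1 s | movement-segment padding |
| GA (`ga_config()`) | Table above | population 20, stall 30 @ 0.01, etc. |
| `nw`, `nfft` | 4, 512 | multitaper bandwidth and window |
| `alpha_band`, `beta_band` | 8--13, 20--30 Hz | ERD/ERS bands |

Problem sizes used by the packaged validation runs were chosen to keep a
full re-run comfortable on a laptop: sessions of 60--100 trials,
reduced GA budgets (at most 40 generations; 6 for the null-decode
scenario, whose channel selection cannot matter), and 8--10 outer folds.

# Known limitations

* The beta event-related synchronization is reported as a *relative*
  power change like the alpha ERD (a flag would be needed for absolute
  change); only the alpha convention is unambiguous in the field.
* No multiple-testing correction is applied across channels in the
  scalp maps by default (`alpha = 0.05` per channel), matching common
  per-channel-dot topographies; correct externally if needed.
* The ICA-cleaned decoding scenario is not implemented; externally
  cleaned recordings can be passed straight to `outer_cv()`.
* `sign_test()` is exact but two-sided only; one-sided hypotheses are
  out of scope.
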