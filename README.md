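# tapdecode

Decoding continuous finger-tapping kinematics from delta-band scalp EEG.

`tapdecode` is an R package for researchers studying non-invasive
brain–machine interfaces and movement-related EEG. It implements, end to
end, the analysis of a self-paced finger-tapping experiment in which a
data glove records the index-finger metacarpophalangeal (MCP) joint
angle while a 65-sensor net records EEG:

* a **lag-embedded linear decoder** reconstructing the joint angular
  velocity from the derivative of delta-band (0.1–3 Hz) EEG,

  θ′(t) = Σᵢ Σₖ b_{ik} S′ᵢ(t − τₖ),  τₖ = 0, 50, …, 300 ms,  N = 47, L = 7,

  fitted by ordinary least squares and scored as the Pearson correlation
  *r* between predicted and observed velocities on held-out trials;
* **genetic-algorithm channel selection** (bit-string population of 20,
  rank scaling, stochastic universal sampling, scattered crossover,
  uniform mutation, elitism, a 30-generation stall rule) whose fitness
  is the median *r* over an 8-fold inner cross-validation, nested inside
  a 10-fold outer cross-validation so that selection never sees test
  data;
* **movement kinematics analysis**: 5%-of-peak-speed onset/offset
  detection, per-trial statistics (trial length, tapping speed, rest,
  extension, range of motion) and Thomson multitaper spectra (NW = 4,
  NFFT = 512);
* **spectral topographies**: alpha-band (8–13 Hz) event-related
  desynchronization during movement, beta-band (20–30 Hz) rebound after
  movement, per-lag delta-band correlation maps, and movement-locked
  grand averages, with exact sign tests across trials;
* **decoding control scenarios**: peripheral-sensors-only and
  rest-period EEG, compared by Kruskal–Wallis with Holm-corrected
  pairwise rank-sum tests;
* a first-class **synthetic session generator** producing 500 Hz EEG
  (1/f background, planted lagged coupling, alpha/beta modulation,
  peripheral artifacts) plus a non-uniformly sampled, 0.93°-quantized
  glove trace, with ground truth (true trial bounds, planted channels
  and weights, attainable correlation ceiling √(snr/(1+snr))) for
  quantitative validation.

## Worked example

```r
library(tapdecode)

ses <- generate_session(tap_params(n_trials = 40),
                        default_coupling(snr = 1), seed = 42)
ses
#> <tap_session> 40 trials, 65 EEG channels @ 500 Hz, 245 s
#>   planted snr 1 on {E15, E33, E44}; r ceiling 0.707

summarize_trials(session_trial_table(ses))
#>         statistic   mean       sd      cov
#> 1    trial_length   1.79 0.574465 3.21e-01
#> 2   tapping_speed   1.95 0.967409 4.96e-01
#> 3   rest_position -18.60 0.000199 1.07e-05
#> 4 extension_angle  18.55 0.172529 9.30e-03
#> 5             rom  37.15 0.172566 4.65e-03

cv <- outer_cv(ses, "unmodified", seed = 7, n_folds = 5, inner_folds = 4,
               ga_cfg = ga_config(max_generations = 15,
                                  stall_generations = 10))
decode_report(cv)
#> <decode_report>
#>   5 folds; decoding accuracy r: min 0.78 / Q1 0.79 / median 0.81 / Q3 0.82 / max 0.86
#>   channels above the binomial selection threshold (count >= 5): 3

head(selection_histogram(attr(cv, "masks"), attr(cv, "labels")))
```

The decoder recovers the movement trajectory well above the planted
single-lag ceiling of 0.707 (the 7-lag design whitens the 1/f
background), and the three channels flagged by the binomial
selection-frequency threshold are exactly the three carrying the planted
coupling. Decoding the same sessions from rest-period EEG
(`outer_cv(ses, "rest", ...)`) yields median *r* ≈ 0, and
`compare_scenarios()` quantifies such contrasts.

See the methods vignette (`vignettes/decoding-methods.Rmd`) for the
model, the preprocessing chain, the GA configuration, the synthetic
generator's assumptions, and the reasoning behind every numerically
consequential choice.

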