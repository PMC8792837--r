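---
title: "Motion recognition from rate-of-stress-change force myography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion recognition from rate-of-stress-change force myography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the signal model

Force myography (FMG) records the pressure patterns that contracting
muscles impose on the skin surface. Piezoelectret film sensors are a
particular FMG transducer: a charged polymer film whose output voltage is
proportional to the *rate of stress change* (RSC) in its normal
direction. Two properties define the signal this package processes:

1. **Transience.** The sensor outputs a burst while pressure is changing
   (motion onset and offset) and *exactly nothing* under static pressure
   (a held contraction, or rest).
2. **Antisymmetry.** Because the stress returns to baseline when the hand
   relaxes, the onset and offset bursts integrate to equal and opposite
   areas; the RSC integral over a completed motion epoch is zero.

The synthetic generator (`simulate_session()`) produces signals with
exactly this structure. For each motion class, a *template* assigns each
channel a signed stress plateau (the pressure level reached mid-motion)
and rise/hold/fall durations. The stress trajectory is a raised cosine:

$$ s(t) = \frac{p}{2}\left(1 - \cos\frac{\pi t}{t_\mathrm{rise}}\right)
   \quad (0 \le t \le t_\mathrm{rise}), $$

constant at $p$ through the hold, and a mirrored ramp back to zero. The
raised cosine is $C^1$-smooth, so the emitted RSC bursts are half-sine
lobes — the shape one sees in real piezoelectret traces. The emitted
samples are the *discrete derivative* of the sampled stress,

$$ \mathrm{RSC}[n] = \big(s(t_n) - s(t_{n-1})\big)\, f_s , $$

rather than the analytic $\dot s$ evaluated at $t_n$. This choice makes
the two defining properties hold *exactly* in the sampled data: hold
samples are identically zero (differences of a constant), and the epoch
sum telescopes to $s(\mathrm{end}) - s(0) = 0$ to machine precision.
Gaussian sensor noise is then added i.i.d. per sample and channel.

### Generator parameters

| parameter | default | meaning |
|---|---|---|
| `n_channels` | 8 | forearm sensor count |
| `classes` | 6 templates | HC, HO, WP, WS, WE, WF |
| `n_repetitions` | 30 | repetitions per class |
| `fs_hz` | 100 | sampling rate (Hz) |
| `epoch_s` | 2 | motion epoch (s); the motion completes inside it |
| `sensor_noise_sd` | 0.02 | additive noise sd (arbitrary pressure-rate units) |
| `separability` | 1 | scales between-class template differences; 0 = identical classes |
| `duration_jitter` | 0.1 | ±10% per-repetition jitter on rise/hold/fall |

Plateau patterns are drawn once per seed: a random sign and a magnitude
in [0.4, 1.6] per class and channel, scaled by `separability`. Classes
therefore differ in amplitude *and* direction across channels, pairwise
template distances are exactly linear in `separability`, and
`separability = 0` is a built-in chance-level control. Template
durations are rise 0.70 s, hold 0.25 s, fall 0.70 s for every class: the
acquisition protocol this emulates instructed subjects to complete each
motion within the 2-s epoch *without holding* the contraction, so the
dynamic ramps carry most of the epoch and the static hold is brief.
Signal amplitudes are arbitrary units throughout — no physical
calibration of the films is attempted. The ±10% duration jitter (drawn
per repetition) prevents analysis windows from being trivially
time-aligned across repetitions; rest periods between repetitions are
not emitted, since the analysis concatenates motion epochs only.

## Preprocessing

**Notch filter.** Power-line interference is removed with a zero-phase
notch at `notch_hz` (default 50 Hz). Below Nyquist this is a biquad with
unit-circle zeros at the notch frequency (infinite rejection at exactly
$f_0$, DC gain exactly 1, quality factor `q = 30`), applied
forward–backward with mirror-reflection padding; the padding length
follows the pole ring-down time so edge transients cannot reach the
retained samples. Mirror (even) reflection matters here: an odd
(point-symmetric) reflection injects a DC offset step at the junction
that a notch passes unattenuated. At the default 100 Hz sampling rate
the 50 Hz notch sits exactly at Nyquist, where the biquad degenerates
(its poles land on the unit circle). The implementation then substitutes
a zero-phase windowed-sinc FIR low-pass (order 30, cutoff 0.9·Nyquist,
coefficients normalised to exact unit DC gain) — it keeps a true zero at
Nyquist, removes the line-frequency band, and leaves a ≤1% ripple
passband, where a naive two-tap averaging kernel would attenuate a 10 Hz
component by ~10%. A warning flags the substitution.

**Segmentation.** Filtered repetitions are concatenated per class and
cut by a sliding window (default 300 ms length, 100 ms increment):
window starts are $0, I, 2I, \dots$ and the count is
$\lfloor (L-W)/I \rfloor + 1$. Each window is attributed to the
repetition containing its first sample. Because windows are cut from the
concatenation, a window may straddle two repetitions of the same class;
`straddle = FALSE` drops such windows for strictly leak-free
cross-validation (the default keeps them, matching the
concatenate-then-window procedure).

**White-noise contamination.** `add_white_noise()` adds Gaussian noise
whose sd is `ratio_pct`% of the per-channel RMS of the matrix it is
given — the *amplitude* reading of a "noise ratio", chosen over a power
reading because visible waveform distortion should only appear at high
ratios. In the pipeline (`noise_sweep()`), the reference RMS is computed
per channel over the *whole stacked session*, not per recording: circuit
noise has one fixed amplitude, and a per-recording reference would give
every motion class its own noise floor — a class-identity leak that
makes accuracy *rise* with noise. Contamination happens on the raw
signals, before filtering and segmentation.

## Features

Thirteen time-domain statistics are computed per window per channel
(`compute_feature()`, canonical order `feature_ids()`), assembled
channel-major into the feature matrix. Three definitional choices:

* **AAC** divides the $N-1$ successive differences by $N$ (not $N-1$),
  so the identity $\mathrm{AAC} \cdot N = \mathrm{WL}$ holds exactly.
* **KURT** is the normalised-moment form used in this literature:
  $\frac{(1/N)\sum (|x_i| - \bar x)^2}{\big((1/N)\sum x_i^2\big)^4}$
  with $\bar x$ the *signed* mean. This is not the conventional
  kurtosis: it has homogeneity degree −6 under amplitude scaling, and it
  is the one feature that is not invariant to a sign flip of the window
  (the other twelve are even functions). Fidelity to the published form
  comes first; `kurt_standard = TRUE` substitutes the conventional
  $m_4/m_2^2$ of the centred samples. The all-zero window (reachable on
  silent hold segments) is defined to have KURT 0.
* **LOGD** floors $|x_i|$ by machine epsilon inside the log, so silent
  windows stay finite.

## Classifiers

`classifier_spec()` declares one of four families; everything a spec
leaves open is a logged default:

* **LDA** — pooled within-class covariance Gaussian discriminant,
  written in-package so that a singular pooled covariance can fall back
  to a small ridge (10⁻⁶ × mean diagonal). Cross-checked against the
  reference implementation in `MASS` in the test suite.
* **KNN** — K = 3, Euclidean distance on standardised features. Vote
  ties break to the *single nearest neighbour's* class, which keeps
  prediction deterministic.
* **ANN** — a fully connected network with two sigmoid hidden layers of
  16 and 6 units and a softmax output, trained by L-BFGS on the
  cross-entropy loss with a light L2 penalty (10⁻⁴), Glorot-uniform
  initialisation from a fixed seed, 500-iteration cap. Written
  in-package because the two-hidden-layer topology is fixed and
  single-hidden-layer fitters do not express it.
* **SVM** — RBF kernel, one-vs-one: one binary machine per unordered
  class pair ($N(N-1)/2 = 15$ for six classes), trained via `e1071`.
  The class vote is computed from the pairwise decision values; vote
  ties go to the largest summed signed margin, then the lowest class
  index. The kernel width defaults to the median heuristic (1 / median
  pairwise squared distance of standardised training rows).

All four standardise features with training-fold statistics by default:
the 13 features span wildly different scales (SSI is quadratic, TM5
quintic in amplitude), and distance-based classifiers would otherwise be
dominated by the largest-scale column. Constant columns get scale 1 and
a warning rather than a division by zero.

## Evaluation

Accuracy is correct test windows / total test windows × 100. The
cross-validation fold unit is the **repetition**: each class's
repetition indices are split into `n_folds` contiguous blocks (30
repetitions, 4 folds → 8/8/7/7) and windows follow their repetition.
Window-level folds would place near-duplicate windows from one
repetition on both sides of the split and inflate accuracy. The reported
`ca_pct` is the accuracy pooled over all folds — which makes it exactly
the label-frequency-weighted mean of the per-class accuracies (the
diagonal of the row-normalised confusion matrix); the across-fold sd is
reported alongside. Where the original study reports across-subject
variability, multiple seeded sessions stand in for subjects.

**SFS** grows the feature set greedily over feature *types* (each
evaluated jointly across all channels), ties broken in canonical feature
order. The selected set is the smallest step within `parsimony_margin`
(default 1.0 accuracy point) of the best step: a two-feature set that is
half a point below a four-feature set should win.

**Sweeps.** `window_sweep()` re-segments and re-validates per window
length at a fixed increment. `noise_sweep()` contaminates the raw
session per ratio and noise seed and runs the full pipeline; its
ratio-0 rows reproduce the clean pipeline exactly.

## What the generator emulates — and what it does not

The synthetic sessions reproduce the *structure* the analysis relies on:
transient antisymmetric bursts, class-specific multichannel
amplitude/direction patterns, trial-to-trial timing jitter, additive
sensor noise, and the session protocol (6 × 30 × 2 s at 100 Hz). Tests
passing on these sessions show the pipeline is correct and that its
qualitative trends (accuracy rising steeply from 100 ms to 300 ms
windows; accuracy degrading monotonically with added noise; chance-level
accuracy when class structure is removed) emerge as expected.

They do not show that real recordings reach any particular accuracy.
Real RSC data differ in ways the generator does not model: correlated
multi-muscle activation across channels, within-class shape variability
beyond duration jitter, baseline drift, and motion-specific burst
morphology. One consequence observed in the package's own sweeps: the
synthetic pipeline is *more* noise-sensitive than the original
recordings were reported to be, because class-discriminative energy is
concentrated in the burst lobes — windows over ramp transitions and
epoch tails carry little signal energy and are swamped once the noise sd
is a substantial fraction of the session RMS. The white-noise sweep
should therefore be read as a monotone-degradation check, not as a
quantitative robustness claim about the hardware.

## Numerical choices and problem sizes

* Window counts, fold blocks and boundary attribution are pure integer
  arithmetic, tested against brute-force enumeration.
* Zero-phase filtering uses mirror padding sized to the filter ring-down;
  both filter paths have exactly unit DC gain.
* Deterministic seeding throughout: session seed → templates, jitter and
  sensor noise; classifier seed → ANN initialisation; noise seed →
  contamination draw. Identical configuration and seeds give
  byte-identical reports (KNN/LDA/SVM are deterministic; the ANN is
  deterministic under a fixed seed).
* Examples and tests run on the full default protocol (3 588 windows of
  30 samples × 8 channels) for headline numbers, and on reduced sessions
  (4 channels, 4–8 repetitions) for property checks; feature-selection
  contracts are verified against exhaustive subset search on a 4-feature
  pool, where exhaustive evaluation is cheap.

## Known limitations

* No frequency-domain or time–frequency features; the analysis is
  time-domain only.
* No real-time decision layer, majority-vote post-processing, or
  subject-transfer evaluation.
* The notch filter's quality factor and the ANN's training schedule are
  conventional defaults, not values fitted to hardware.
* The ANN's loss surface is non-convex: permuting training rows can
  change its fit (unlike LDA/KNN/SVM, whose predictions are
  permutation-invariant); reproducibility is guaranteed only at fixed
  seed and row order.
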