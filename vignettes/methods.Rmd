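---
title: "Models, generators and numerical choices in vcfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, generators and numerical choices in vcfatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, what the
synthetic-data generator does and does not emulate, and where genuinely open
design choices were resolved.

## 1. The analysis chain

**Continuous EEG.** Each channel is high-pass filtered with a zero-phase
Hamming windowed-sinc FIR (cutoff 0.5 Hz, order 1128), power-line noise is
suppressed with a cascade of zero-phase biquad notches at 50 Hz and its
harmonics (1 Hz notch width), and eye blinks are attenuated with
wavelet-enhanced ICA (wICA): ICA components selected as artifactual are
wavelet-transformed (periodic Daubechies-4, 5 levels) and coefficients above
a scaled universal threshold are zeroed, so sub-threshold neural structure is
retained rather than the whole component being discarded. Band powers in
Delta (0.5–3.5), Theta (4–7.5), Alpha (8–12.5) and Beta (13–30 Hz) are Welch
estimates (8 Hamming segments, 50% overlap) in non-overlapping 3-min
windows, normalized by the PSD integral over 0.5–30 Hz. Trends over windows
are ordinary least squares with a two-sided slope test.

**ERP path.** 0.5–30 Hz two-way least-squares FIR band-pass, epochs −0.2 to
+0.8 s around target onsets with pre-stimulus-mean baseline correction,
rejection of trials exceeding ±100 µV on any channel, subject averages then
unweighted grand averages. Onset latency is the first sustained (≥10 ms)
departure beyond 2 pre-stimulus SDs inside the component search window
(N2 0.2–0.35 s, P3a 0.25–0.5 s, P300 0.3–0.7 s). Time-point-wise models:
`amplitude ~ phase + (1|subject)` and the item models
`after ~ before + item_before + item_after + (1|subject)` (mood items) /
`after ~ before + item_after + (1|subject)` (fatigue items), with the
after-item effect standardized by the residual SD. The covariate `before`
controls regression to the mean.

**ECG path.** Pan-Tompkins (5–15 Hz zero-phase band-pass, 5-point
derivative, squaring, 150 ms integration, adaptive dual thresholds, 200 ms
refractory period, search-back at reduced threshold), R times refined to the
band-passed peak. RR intervals outside [200, 3000] ms or jumping >30% are
removed and interpolated. Time-domain indices per 3-min window: HR =
60000/mean(RR); RMSSD; pNN50 with, by default, the *total number of RR
intervals* as denominator (the instrument's literal definition; the
conventional successive-differences denominator is available via
`pnn50_denominator = "differences"`); SDRR. Frequency-domain indices come
from the RR series cubic-spline-resampled to 4 Hz: Welch PSD with linear
per-segment detrend, LF = 0.04–0.15 Hz, HF = 0.15–0.4 Hz, total power from
0.003 to 0.4 Hz (DC excluded; the lower edge is configurable because the
instrument description leaves it open).

**Statistics.** Paired condition comparisons use the Wilcoxon signed-rank
test (exact for ≤25 untied pairs, normal approximation with continuity
correction otherwise). Multiplicity is handled by Benjamini–Hochberg with
frozen families: across time samples within one channel × model × item for
the ERP models; across windows within one index × channel for window-wise
comparisons; across the item × index cells within one linking model. Mixed
models are fit by REML with `lme4`; a singular or failed fit falls back to
the fixed-effects-only OLS model with a flag (at zero random-intercept
variance the two coincide, which is also how the OLS-oracle tests pin the
implementation down). Fixed-effect p-values use t statistics on
n − rank(X) − (n_groups − 1) degrees of freedom — the within-subject residual
df, equal to the paired-t df in the balanced phase design. `lmerTest`-style
Satterthwaite df are not available in this environment; the chosen df are
conservative for the balanced designs used here.

## 2. What the generator emulates

Each synthetic channel is the sum of (i) a 1/f-power band-limited (0.5–30 Hz)
Gaussian background, (ii) three equal-amplitude sinusoids per band whose
common power envelope follows a linear trajectory, (iii) stereotyped
300-ms frontal-dominant blink bumps at Poisson times, and (iv) a 50 Hz
line-noise sinusoid. Total 0.5–30 Hz power is held constant per channel:
an injected normalized-power drift in one band is balanced by proportional
counter-drifts of the *oscillatory* power of the non-drifting bands. This
conservation rule is what makes the injected slope exact in expectation —
the stationary background then only shifts intercepts, never slopes, so
recovery tests do not depend on how precisely the background's band
fractions are estimated. The ground truth records the effective slope of
every band, including the counter-drifts.

RR series: beat times accumulate RR = 60000/HR(t) + σ(t)·x(t), where HR(t)
is linear in the 3-min-window index and x(t) is a unit-variance sum of two
band-limited processes (LF 0.04–0.15 Hz, HF 0.15–0.4 Hz) with power ratio
exp(target ln[LF/HF]). Each band process is a stratified-frequency,
random-phase superposition of 64 sinusoids — evaluable at the irregular beat
times and with closed-form autocorrelation ρ(τ). The envelope σ(t) either
stays constant (`rr_jitter_sd`, default 30 ms) or is derived analytically
from a requested linear profile of one windowed index:
σ = SDRR; σ = RMSSD / √(2(1−ρ(RR̄))); σ = 50 / (Φ⁻¹(1 − pNN50/200) ·
√(2(1−ρ(RR̄)))). These inversions are deterministic mappings from the stated
target to generator parameters, fixed before any result is seen. The ECG
trace places a minimal QRS-like template (Q/R/S Gaussians plus a low T wave,
1 mV R peak) at each beat time; R-peak detectability, not cardiac
morphology, is the goal.

Questionnaires: a latent fatigue value per subject × condition (persistent
subject trait + occasion noise, plus a standardized shift in the
videoconference condition) drives ordinal items through a thresholded
latent-variable model; all 18 fatigue items and the 8 unpleasant mood
adjectives load +0.8, the 8 pleasant adjectives −0.8.

**What it does not emulate** — and hence what a green test does not
establish: volume conduction and channel covariance (channels are
independent except for blinks), non-stationarities other than linear drifts,
muscle/movement artifacts, realistic P/T-wave morphology or ectopy,
respiration-driven HF coupling, and item-specific questionnaire content.
Recovery tests demonstrate that the pipeline measures what the generator
injects; they cannot validate the pipeline against physiology it never sees.

## 3. Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `sampling_rate` | 512 | Hz | amplifier rate emulated |
| `lecture_duration` | 3000 | s | 50-min session, 16 complete 3-min windows |
| `band_baseline` | 0.42/0.16/0.23/0.15 | – | typical awake normalized band shares; must sum ≥ ~0.94 so the bands dominate the 1/f background within 0.5–30 Hz |
| `band_drift` | condition defaults | normalized power / s | published videoconferencing slopes (Fz Theta 2.724e-6; Alpha per channel) |
| `hr_baseline`, `hr_slope` | 75, −0.1482 | bpm, bpm/window | seated young adults; published HR decline |
| `rr_target` | rmssd 30 + 0.4955/window | ms | published RMSSD rise; one envelope controls one index at a time |
| `lf_hf_log_ratio` | 0.3 | – | mild sympathetic dominance at baseline |
| `blink_rate`, `blink_amplitude` | 12/min, 100 µV | | typical spontaneous blinking, frontal-dominant |
| `latent_fatigue_effect` | 0.8 | SD | moderate-to-large self-report effect |
| wICA `kurtosis_cutoff` | 5 | – | blinks are strongly leptokurtic; ongoing EEG is not |
| rejection threshold | 100 | µV | trial-level artifact bound |

Slope-unit conventions are deliberate: EEG drifts are injected and recovered
in normalized power **per second** (window mid-point time axis), HR/HRV
drifts **per 3-min window** (window index axis). The source report's slope
units are internally inconsistent (a per-second HR slope of −0.148 would be
unphysiological; per-window EEG slopes of ~3e-6 implausibly small), and the
time axis is never stated, so the package fixes its own self-consistent
convention per modality and uses it on both the injection and the recovery
side rather than guessing the original convention.

## 4. Numerical choices and degenerate inputs

* FIR edges: reflect padding of one filter length before zero-phase
  (centered, type-I) convolution; FFT convolution zero-pads to 5-smooth
  lengths.
* The ERP band-pass is the unweighted least-squares (truncated Fourier
  series) FIR applied forward and backward; the quoted passband/stopband
  contracts refer to the two-pass magnitude.
* The 0.5 Hz high-pass has its −6 dB point exactly on the Delta band edge,
  so it necessarily trims lower-Delta background power (~9% relative on 1/f
  background). The artifact-free "pass-through" contract therefore covers
  the comb and wICA stages; the high-pass is held to its frequency-response
  specification instead.
* FastICA uses one-unit deflation with the logcosh contrast (tolerance 1e-4,
  500 iterations, fixed internal init seed). The symmetric variant
  oscillates on the near-Gaussian subspace of ongoing EEG; deflation lets
  the heavy-tailed blink component converge in a few iterations. If any
  component fails to converge the recording is returned unmodified with a
  warning and an `uncleaned` flag.
* Welch segments detrend by mean removal (linear detrend for RR spectra);
  a window containing non-finite samples becomes a missing window and is
  excluded from trends. A constant feature series gets slope 0, p 1.
* LF/HF band edges: LF includes 0.15 Hz, HF starts strictly above it, so
  the normalized powers are integrals of disjoint bands and LF_nu + HF_nu
  ≤ 1 holds structurally. ln[LF/HF] is missing when HF power is zero.
* Wilcoxon with all-zero paired differences returns p = 1. Constant item
  scores make an item effect undefined (missing, with a warning).
* `order_effect_check` uses sum-to-zero factor coding, so main effects are
  averages over the other factor; estimates are half the group difference.
* Oddball inter-stimulus interval is fixed at 1.0 s onset-to-onset
  (configurable): only the 500 ms presentation time is documented, and 500
  events at 1 Hz stay close to the stated few-minute task length while
  keeping epochs non-overlapping. Whether consecutive targets were
  constrained is unknown; sequences here are unconstrained random draws.
* Standard events receive the target template at 30% amplitude so that the
  target > standard contrast the oddball design relies on exists in
  synthetic data.
* The three ZEF items beyond the 5 × 3 dimension structure are kept in an
  "unassigned" bucket that contributes only to the overall mean; their
  dimensional assignment is not recoverable from the instrument description.
* Eq.-(4)/(5)-style linking models pool both lecture conditions without a
  condition fixed effect, as written; a condition-covariate variant is
  available behind `condition_covariate = TRUE`.
* The per-channel vs pooled question for the phase model is resolved by
  fitting per channel (the item models pool channels with the subject as the
  grouping factor, as described for those models).

## 5. Known limitations

Single-envelope HRV injection cannot satisfy independent SDRR, RMSSD and
pNN50 profiles simultaneously — each recovery experiment injects one index.
The pNN50 inversion assumes near-Gaussian marginals (exact only in the
many-sinusoid limit). wICA quality is bounded by the mixing-matrix estimate
on short recordings. EDF support is the minimal 16-bit subset the pipeline
needs (no annotations). All empirical claims made here are computed by the
test suite or the acceptance script; none are quoted from elsewhere.
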