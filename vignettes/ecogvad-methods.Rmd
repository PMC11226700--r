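---
title: "Speech event detection from ECoG: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech event detection from ECoG: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Speech brain–computer interfaces need to know *when* speech is
happening before they can decode *what* is being said. For overt speech
the audio track provides that timing; for imagined (covert) speech there
is no behavioral output at all, which is precisely why imagined speech is
the clinically interesting mode for locked-in patients — and why it is
hard: there is no ground truth to align trials with. This package
implements a frame-wise speech-event detector for ECoG (a neural
voice-activity detector), a surrogate-labeling scheme that makes
imagined trials trainable, and the statistics to decide whether a
detector — possibly trained on another speech mode or another subject —
performs above chance.

## The detection model

Per channel, the referenced and notched 256 Hz signal is decomposed into
seven bands (delta 0.5–4 Hz through high-gamma 70–120 Hz) with 4th-order
Butterworth band-passes applied forward–backward (zero phase). Each
band's Hilbert envelope — the magnitude of its analytic signal — is
smoothed with a single heavy 4th-order zero-phase low-pass at 0.25 Hz.
That one smoother replaces the usual cascade of envelope smoothing,
output smoothing and post-threshold debouncing: the detector's continuous
output is already slow, so a plain threshold yields clean event windows.
The trade-off is temporal resolution, discussed below.

A frame at time $t$ is the 21-vector of the seven smoothed envelopes at
$t-125$ ms, $t$, $t+125$ ms (band-major, lag-minor column order),
z-scored with training-set statistics. The detector is ordinary least
squares onto labels $y \in \{-1,+1\}$; the continuous output is
thresholded at 0, with exactly 0 classified as speech (the stated rule is
that a *negative* value is silence). OLS is deliberately unregularized —
21 predictors against thousands of frames is well posed — though a ridge
option exists.

Because decoding weights are not interpretable band-by-band, band
contributions are reported as Haufe activation patterns
$a \propto \mathrm{Cov}(X)\,w / \mathrm{Var}(w^\top X)$, computed on each
training fold, averaged over folds, then scaled so the maximum absolute
entry is 1. The "gamma activation" summary is the mean of the six
entries of the two gamma rows (all three lags; the lag treatment was an
open choice and averaging is the symmetric one).

Evaluation is leave-one-trial-out: z-scoring and fitting use the
training trials only, accuracy is the percent of correct frames on the
held-out trial, and the reported score is the unweighted mean over
trials. Datasets are built to contain exactly as many speech as silence
frames per trial, so 50% is the chance level by construction.

## Labels

**Performed / perceived trials.** Frames inside the observable speech
window (onset of the first phone to offset of the last, boundaries
inclusive) are +1, others −1. Balancing keeps every speech frame and an
equal number of silence frames drawn contiguously around the window,
split as evenly as possible before/after it; when the post-window
segment is short (next trial starts), the deficit moves before the
window, and odd counts favor "before" for the same reason.

**Imagined trials.** The timing is borrowed from the performed trials:
all performed trials are aligned at the go cue and their 0/1 labels
averaged per frame. The maximal contiguous span with average
strictly above 0.9 becomes the surrogate speech window — onset delay
overestimated, offset underestimated, by construction conservative.
Silence is taken before the go cue where the average is strictly below
0.1, plus at most 500 ms at the very end of the trial (capped to favor
pre-go-cue data, where the probability of covert speech is essentially
zero). Post-go-cue frames meeting neither rule are ambiguous and
discarded. The implementation is verified against an independent
brute-force evaluator of these rules on a thousand random label
matrices.

**Passive dataset.** A 4 s window centered on the task cue of each
imagined trial, all frames labeled no-speech: no intentional imagined
speech should occur there, so accuracy on this set reads as a
specificity. An electrode whose passive accuracy falls strictly below
50% likely responds to the visual cue rather than to speech; its
reported score is clamped to 50% and flagged. How the original analysis
labeled this window is not fully specified; the all-silence reading is
the one that implements the stated purpose ("reject electrodes that
respond to the cue") and is documented as a choice.

## Multi-electrode, transfer, pooled models

Electrodes are ranked per training fold by the maximum absolute
band-averaged Pearson correlation between features and labels (constant
features count as zero; ties break by electrode index for
reproducibility). The top-$k$ single-electrode continuous outputs feed a
second linear regressor, thresholded like the first. The optimal $k$
starts from the single-electrode incumbent and is updated whenever a
larger model beats the *running* incumbent (one-sided paired Wilcoxon
over per-trial accuracies, $\alpha = 0.05$); if no model ever wins, the
highest mean accuracy is returned.

Transfer between speech modes or subjects fits one model on the full
source dataset and scores each target trial, both datasets z-scored with
their own full-set statistics — faithful to the offline evaluation
protocol, and explicitly not a deployable causal system (target
statistics are used at test time). The pooled multi-subject model
equalizes trial counts by seeded subsampling, z-scores per subject,
and cross-validates with folds holding out exactly one trial per
subject.

## Statistics

The permutation test reverses all labels of a random
$\lfloor T/2 \rfloor$-subset of trials and re-runs the entire LOTO
cross-validation; reversing whole trials rather than frames keeps the
low-frequency label structure. $p = (N+1)/(n_\text{perm}+1)$ with $N$
counting null accuracies at least as large as the observed one (the
conservative $\ge$ reading; configurable). For transfer evaluations only
the target trials' labels are reversed and the fixed model's decisions
are re-scored.

Re-running LOTO thousands of times is made cheap by an algebraically
exact shortcut: OLS-with-intercept predictions are invariant to feature
standardization, so each fold's normal-equations matrix is independent
of the label signs and can be factorized once, while the right-hand side
flips per reversed trial. The test suite asserts equality with naive
fold-wise-z-scored re-runs at machine precision, so the fast path is a
verified implementation, not an approximation.

**Calibration caveat.** Half-reversal is not a permutation group (two
half-reversals compose to something else), so the test is only
approximately exchangeable. On independent balanced null frames the
measured type-I error at $\alpha = 0.05$ is slightly above nominal
(about 0.06–0.08 across 10–60 trials; the acceptance suite measures
this at the task's 20 trials and asserts it stays inside the 95%
binomial band around 0.05). On real envelope features the frames within
a trial are almost perfectly dependent — the 0.25 Hz smoother gives each
trial only a handful of effective samples — and the small-sample
anticonservatism grows; at very small trial counts the effective level
can roughly double. At the $\alpha = 0.01$ and $p < 0.001$ levels used
for scientific claims the practical impact is small, but p-values from
few trials should be read with this in mind. A related refitting effect
shifts the *mean* of the null distribution slightly below 50%: with
exactly half the trials reversed, the training majority opposes each
held-out trial by one trial, so strong-signal datasets yield null means
a point or two under 50, converging to 50 as trials grow. The
acceptance target measures this mean on a 60-trial dataset, where it
sits within the stated ±2 band.

## The synthetic generator

Each electrode is $\sum_b a_b\,(1 + m_b(\text{mode})\,s(t))\,n_b(t)$:
unit-variance Gaussian noise band-passed into band $b$ with the same
zero-phase Butterworth the analysis uses (so the feature model is
realizable and $m$ maps directly onto envelope change), amplitude
modulated by the ground-truth speech indicator $s(t)$ smoothed with
250 ms raised-cosine ramps (avoiding steps the 0.25 Hz smoother would
ring on). Baseline amplitudes default to a 1/f profile
($a_b \propto 1/f_\text{center}$). Optional 50 Hz line noise and a
300 ms cue-locked broadband burst provide test vehicles for the notch
and the passive-exclusion rule.

The paradigm follows the recorded task: 1 s task cue, 2 s preparation
plus up to 1 s uniform jitter, go cue, utterance. Where the task
description fixes no value, defaults were chosen once for realism and
kept: utterances mean 2.5 s (SD 0.4) emulating short controlled
sentences, voice onset 0.5 s (SD 0.15) after the go cue, 2 s of
inter-trial silence, 20 trials per mode. Imagined trials expose no
behavioral timing in any observable table — their windows live only in
the separate ground-truth file the pipeline never reads.

Modulation profiles encode the qualitative region/mode physiology the
detector should recover: motor-like electrodes raise gamma and depress
low frequencies in every mode (weakest for perceived speech);
temporal-like electrodes raise gamma for performed/perceived but show
*no* gamma change for imagined speech while low-frequency modulation
persists; "other" electrodes carry nothing. The magnitudes are tuning
knobs of the simulator, not estimates of any patient's physiology.

**What a green test does and does not establish.** The generator's
carriers are stationary within bands and share the analysis filter bank,
so band separability, envelope calibration ($({1+m})^2$ power ratios)
and activation-pattern sign recovery are exact targets. It does not
emulate cross-frequency coupling, evoked transients, electrode drift,
interictal activity, articulatory acoustics or cortical geometry —
passing tests validate the pipeline's machinery and its qualitative
band-region-mode logic, not clinical performance numbers.

## Numerical and design notes

- **Filters** are designed as analog Butterworth prototypes, frequency
  warped, bilinear transformed, and run as cascaded biquads —
  numerically robust at the extreme normalized cutoff of the 0.25 Hz
  smoother, where a transfer-function form would be ill-conditioned.
  Zero-phase filtering uses odd-reflection padding of three time
  constants of the lowest cutoff; start-up transients remain only in
  the padded margins, and frames within 125 ms of a record edge are
  dropped.
- **Temporal resolution floor.** The 0.25 Hz smoother blurs each speech
  on/offset over a transition zone of a couple of seconds. Frames there
  are intrinsically ambiguous, which caps attainable LOTO accuracy as a
  function of utterance length regardless of modulation depth — with
  2.5 s utterances the ceiling sits just under the strong-signal
  acceptance threshold, so that criterion probes the idealized electrode
  with 4 s utterances. This mirrors the method's own note that the
  smoother "could be adapted if shorter sentences were considered".
- **Null electrodes and dependence.** Because frames are nearly
  degenerate within a trial, per-frame binomial intervals are
  meaningless; chance-level checks count trials with majority-correct
  frames against Binomial($T$, ½).
- **Transfer with collinear lags.** The three lag columns of a band are
  almost identical after smoothing; OLS happily loads large
  opposite-signed weights on them (a curvature combination). Within a
  mode this is fine, but when a model fitted on a dataset with *no*
  informative bands is transferred to one with a strong shared envelope
  component, the projection lands far from 50% with a random sign —
  which is why a lucky "significant" imagined→performed gamma-only
  transfer can occur. The acceptance check therefore reads transfer
  failure from the stable direction (performed→imagined) and from the
  low-band-versus-gamma contrast, aggregated over seeds.
- **Degenerate inputs.** Constant feature columns z-score to zero
  (never divide by zero) and count as zero correlation in ranking;
  single-class labels, empty windows, gamma-less patterns, mismatched
  feature counts and overlapping trial layouts raise early, named
  errors; single-channel grids are zeroed by strict per-grid CAR (a
  consequence of the definition) but left unreferenced by the
  orchestration wrapper, which says so.
- **Determinism.** Every stochastic step (paradigm, synthesis,
  permutations, subsampling) takes an explicit seed; pipeline tables are
  stamped with the seed and a config hash, and byte-identical reruns are
  part of the test suite.

## Limitations

Offline and zero-phase throughout — not a causal, real-time detector.
EDF input is out of scope (recordings use a plain-text container);
electrode localization, forced audio alignment and acoustic-contamination
checks are outside the package. Cross-subject transfer takes an explicit
electrode pairing and does not infer anatomical correspondence. The
permutation test's mild anticonservatism at small trial counts is a
property of the published scheme itself, measured and documented above.
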