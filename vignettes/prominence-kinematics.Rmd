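---
title: "Measuring gesture-speech timing around acoustic prominence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gesture-speech timing around acoustic prominence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promkin)
```

## The measurement problem

When people speak, prominence-lending hand movements (beats) tend to align
with the acoustically emphasized syllable. Second-language learners of a
free-stress language often misplace lexical stress in cognates — a Dutch
speaker saying Spanish *profeSOR* competes with native *proFESsor* — and
the interesting question is whether the *hand* also carries this
cross-linguistic competition: a "kinematic accent" in which the apex of a
beat movement is pulled in time toward the native-language stress position
even when the voice places stress correctly, and toward the correct target
syllable when the voice is wrong.

`promkin` implements the full measurement chain needed to ask that
question of audio + syllable-boundary + pose-tracking data:

1. **Acoustic prominence nomination.** For each syllable $i$ of a word,
   three cues are extracted — duration $D_i$ (from the boundary tier), peak
   fundamental frequency $F_i$, and peak amplitude-envelope magnitude
   $I_i$ — z-normalized across the syllables of that utterance, and
   combined as
   $$S_i = W_F F^z_i + W_I I^z_i + W_D D^z_i,$$
   with default weights $W_F = W_I = W_D = 0.33$. The syllable with the
   highest $S_i$ is nominated as acoustically most prominent. Because
   nomination is an argmax, equal weights of 0.33 and 1/3 are
   interchangeable, and any common affine transform of a raw cue leaves the
   nomination unchanged (the z-normalization guarantees this).
2. **Speech anchor.** The timing anchor on the speech side is the local
   maximum of the amplitude envelope *within the nominated syllable's
   interval* — deliberately not the word's global envelope maximum, since
   prominence is defined by three cues of which amplitude is only one.
3. **Kinematic apex.** The vertical index-finger position is resampled to
   a uniform 50 Hz grid, orientation-normalized so extension (downward
   motion) is positive displacement from the trial's starting baseline,
   low-passed, and the apex is the global maximum of extension displacement
   in the search window.
4. **Asynchrony.** `asynchrony_ms = (t_apex - t_envelope_peak) * 1000`;
   negative values mean the hand leads the voice.
5. **Inference.** Linear mixed models of asynchrony on a five-level timing
   condition and on a signed syllable-distance predictor, plus an intensity
   model and a logistic accuracy model, all with random intercepts for
   speaker and item.

## Conditions and the item space

Items are cognates characterized by the 1-based L2 target stress position
and the L1 competitor position; `distance = competitor - target` (negative
when the competitor precedes). Trials are classified by production
(`correct_L2`, `incorrect_L1`, `other`) and labeled:

| condition | item type | production | attractor position |
|---|---|---|---|
| `matching_correct` | matching | correct | — (baseline) |
| `precede_correct` | mismatching | correct | competitor before target |
| `follow_correct` | mismatching | correct | competitor after target |
| `precede_incorrect` | mismatching | competitor-stressed | target before competitor |
| `follow_incorrect` | mismatching | competitor-stressed | target after competitor |

`other` productions and off-target productions of matching items carry no
defined attractor direction and are labeled `excluded`; they stay in the
trial table (flagged, countable) but are dropped by the timing models.

## Signal-processing choices

The upstream literature rarely states these exactly, so the package fixes
them explicitly; all are exposed in `extract_params()` and the pipeline
config.

* **Envelope** (`amplitude_envelope`): magnitude of the analytic signal
  (FFT Hilbert transform), block-average decimation to ~1 kHz, zero-phase
  4th-order Butterworth low-pass at 12 Hz, sampled at 100 Hz. 12 Hz keeps
  syllable-rate modulation (2–8 Hz) and discards voicing ripple; the
  intermediate decimation keeps the Butterworth design well-conditioned.
  The envelope is demeaned before filtering so `filtfilt` edge transients
  are negligible, and clipped at zero afterwards.
* **f0** (`f0_track`): short-time autocorrelation, 40 ms frames, 10 ms
  hop, search range 75–500 Hz (mixed-sex adult speech), voiced when the
  normalized autocorrelation peak exceeds 0.45 and the frame is not
  near-silent; parabolic interpolation refines the peak lag so a steady
  200 Hz tone tracks to well under 1 Hz.
* **Missing f0**: a wholly unvoiced syllable gets the *minimum* f0 z-score
  among the voiced syllables, so lack of voicing can never win prominence
  through the f0 cue; the trial is flagged. With fewer than two voiced
  syllables the f0 cue becomes neutral (all zeros).
* **z-scores** use the sample (n−1) standard deviation; a zero-variance
  cue contributes zeros (a neutral cue) rather than NaNs. Both choices are
  scale conventions shared by all syllables, so they cannot change a
  nomination.
* **Ties** in the argmax (scores or flat envelope maxima) resolve to the
  earliest syllable/sample — determinism over arbitrariness.
* **Kinematics** (`preprocess_track`): cubic-spline resampling to 50 Hz,
  zero-phase Butterworth low-pass at 10 Hz (biphasic beat energy is ~1–3
  Hz), baseline from the first 200 ms. An apex on the window edge is
  flagged `apex_at_edge`, not discarded. Body-scaling (dividing by a
  reference length) only rescales amplitude; every timing quantity is
  scale-invariant.
* **Apex search window** defaults to the speech extent ± 500 ms.

## Statistical models

The timing outcome is in milliseconds, so the asynchrony models are
identity-link linear mixed models (`lme4::lmer`); the logistic link is
reserved for the binary accuracy outcome (`lme4::glmer`). The condition
model is fitted without an intercept (`asynchrony ~ 0 + condition`) so
each condition is estimated directly. Random intercepts for speaker *and*
item are the default grouping; this is configurable. p-values use the
large-sample normal approximation on estimate/SE ratios — deterministic
and free of a degrees-of-freedom convention — judged against an adjusted
alpha of 0.016 (consistent with 0.05/3 for three confirmatory questions).
If `lmer`/`glmer` fails on degenerate input (e.g. exactly zero variance),
the fit falls back to `lm`/`glm` and is flagged as such in `converged`.

The gradient model regresses asynchrony on the *signed syllable distance*
(`competitor - target`) over correctly produced mismatching movement
trials. Syllables, not milliseconds, are the distance unit here; the
syllable is the unit in which the stress positions are defined, and it
keeps the predictor exactly known rather than estimated.

## The synthetic study generator

Real recordings of this design are not redistributable, so
`synth_config()` + `simulate_extract()`/`synth_study()` generate complete
studies with known truth. The generator *is* the study design, not a test
dial: 26 speakers × 96 items (48 matching / 48 mismatching, half with
accent marks) × 2 movement conditions, blocked every 6 trials; production
accuracies 0.60 (matching) and 0.53/0.27/0.20 (mismatching
correct/competitor/other); per-condition asynchrony means −48, −88, +45,
−119, +72 ms; trial noise SD 120 ms and speaker/item intercept SDs
40/30 ms. Where the underlying study does not state a value (syllable
durations ~0.17 ± 0.03 s, speaker f0 baselines in two bands around 115 and
215 Hz to emulate a mixed-sex sample and stress the z-normalization,
8 kHz audio, pixel-scale pose amplitudes), realistic values were fixed
once and documented here.

Each syllable is an amplitude-modulated harmonic complex: a Hann amplitude
contour (so the true envelope peak is the syllable center), a flat-plus-
peak f0 contour, random harmonic phases. The produced-stress syllable is
boosted by `cue_boost` between-syllable SDs in all three cues (default
2.5, at which the pipeline re-identifies the produced syllable in >95% of
trials). Movement trials multiply the prominent syllable's amplitude by
1.10, injecting the biomechanical intensity coupling that the
`movement_boost_test` model measures. The hand movement is a smooth
squared-cosine extension–flexion bell in image coordinates whose apex
sits at the true envelope peak plus the trial's generated asynchrony.

Two structural notes. First, 2-syllable words appear only among matching
items: a 2-syllable mismatching cognate has no syllable that is neither
target nor competitor, so the `other` production class would be
structurally impossible for it and realized class proportions could not
match the presets. Second, in gradient mode (`gradient_slope_ms` set) the
generator emits only mismatching items, produced correctly, movement
trials only — the exact population the gradient model consumes — with
per-trial asynchrony mean `slope × distance`.

The generator deliberately does **not** emulate: real coarticulated
speech (the pipeline only consumes envelope, f0 and boundaries, so
vocoder-grade synthesis would add nothing testable), pose-estimation
artifacts beyond white tracking noise, within-speaker drift in cue
weighting, or any biomechanical mechanism — the intensity boost is
injected as a configured effect, not modeled. Passing recovery tests
therefore shows the *measurement chain* is faithful, not that the
generator's simplifications hold in real data.

### Native-speaker verification preset

To verify the metric itself, the package emulates the check of running the
pipeline on native productions: natives stress the right syllable but with
natural cue variability, so nomination agrees with the phonological stress
position only in a fraction of trials (≈0.70 in comparable work).
`calibrate_native_boost()` measures the pipeline-based agreement on
Monte-Carlo simulated native productions over a grid of cue boosts, pools
the grid in a probit regression (agreement is monotone in the boost), and
inverts the fitted curve at the 0.70 target before measuring the achieved
agreement on a fresh sample. A sequential bisection search was tried first
and discarded: each of its accept/reject decisions rides on a single
Monte-Carlo estimate, and one early wrong turn is irreversible, whereas
the pooled regression uses every simulated trial. Typical calibrated
boosts land near 0.9 SD.

## Problem sizes and reproducibility

The package's own validation simulates the full default study (9,984
trials, ~2 minutes on one core at 8 kHz audio), a gradient-mode study
(1,248 trials), and the calibration (~2,200 short utterances). Every
stochastic step consumes a single configured seed; identical configs
reproduce byte-identical datasets, and `scripts/acceptance.R` re-runs the
whole chain from a command-line seed.

## Known limitations

* The acoustic front end is tuned for clean, isolated-word recordings;
  noisy or conversational audio would need a stronger voicing decision and
  possibly a different envelope cutoff.
* Nomination errors (<5% at default boost) slightly attenuate condition
  estimates toward each other; at the study's noise levels this is well
  inside sampling error, but it is a bias, not noise.
* `incorrect_L1` is undefined for matching items (target = competitor), so
  matching items contribute only `matching_correct` and `excluded` trials.
* The apex detector returns the global in-window maximum; multi-beat
  movements would need gesture segmentation, which is out of scope.
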