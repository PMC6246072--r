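---
title: "Modelling binaural speech intelligibility on synthetic room scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling binaural speech intelligibility on synthetic room scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binratio)
```

## The problem

When several talkers or noises compete with a target voice, normal-hearing
listeners exploit two binaural mechanisms to understand speech: *better-ear
listening* (in every time-frequency cell, use whichever ear offers the higher
target-to-interferer ratio) and *binaural unmasking* (interaural phase and
coherence differences between target and interferer let the binaural system
cancel part of the interferer, the effect measured as the binaural masking
level difference, BMLD). Behind-the-ear (BTE) hearing aids move the acoustic
pickup above the pinna; even with purely linear, flat amplification this
distorts the spatial cues — the ear-canal resonance around 2–3 kHz is lost,
high-frequency interaural level differences (ILDs) of lateral sources grow
by several dB because the head baffles the microphones, and interaural time
differences (ITDs) shrink slightly. `binratio` implements a short-time
binaural intelligibility model together with a fully synthetic acoustic
scene stage, so that the aided-vs-unaided / separated-vs-collocated analysis
can be run end to end without any measured head-and-torso data.

## The model

Signals are analysed through a gammatone filterbank with two filters per
equivalent rectangular bandwidth (ERB), by default spanning 80 Hz–10 kHz
(66 bands), and through 24-ms half-overlapping Hann frames (effective
duration about 12 ms). The model takes two inputs: the ear signals of the
target and the ear signals of the *sum* of all interferers.

The target's statistics — band powers at each ear and interaural phase
$\phi_T$ — are computed **once over the whole signal**. Natural speech
pauses in the target would otherwise masquerade as unintelligibility when
framed. The interferer is framed: per band $b$ and frame $t$ we compute the
tapered power at each ear, the interaural phase $\phi_I$ (argument of the
windowed cross-power), and the interaural coherence $\rho$.

Two components are then formed per band and frame:

* **Better-ear ratio**
  $\mathrm{BE} = \min\!\left(c,\; \max_{\text{ears}} 10\log_{10}
  \frac{P_T}{P_I}\right)$, with ceiling $c = 20$ dB. The ceiling exists
  because interferer pauses would otherwise drive the ratio to infinity;
  frames with zero interferer power at both ears sit exactly at the ceiling.
* **Binaural unmasking advantage** (equalization–cancellation form)
  $$\mathrm{BU} = 10\log_{10}
  \frac{k - \cos(\phi_T - \phi_I)}{k - \rho}, \qquad
  k = (1 + \sigma_\varepsilon^2)\, e^{\omega^2 \sigma_\delta^2},$$
  with $\omega = 2\pi f_c$ and internal-jitter constants
  $\sigma_\varepsilon = 0.25$, $\sigma_\delta = 105\,\mu s$ — the standard
  EC-model values, exposed in `ec_parameters()` because they are inherited
  from the model lineage rather than fixed by the experiment this package
  emulates. BU is floored at 0 dB (switchable) and set to zero whenever the
  interferer power vanishes at either ear in a cell.

Per frame, $\mathrm{BE} + \mathrm{BU}$ is combined across bands with
speech-intelligibility-index band-importance weights interpolated to the
gammatone centres (uniform weighting is a switch); the scalar output — the
**binaural ratio** — is the average of the per-frame broadband ratios in
the dB domain. Whether that average belongs in the dB or the power domain
is genuinely open; dB was chosen (and made switchable) because the quantity
being averaged is already a dB-domain SNR-like measure and power-domain
averaging is dominated by the heavy upper tail of reciprocal band powers.
Binaural ratios move inversely with speech reception thresholds (SRTs), so
*differences* between conditions predict SRT differences with inverted
sign, with no free parameters fitted: `ha_disadvantage()` is the unaided
minus aided ratio, `predicted_srm()` the separated minus collocated ratio.
Because BE and BU integrate independently, the predicted spatial release
decomposes exactly into a better-ear and an unmasking share.

A long-term variant (`long_term_model()`) runs the identical computation
with one whole-signal frame. For fluctuating maskers the short-term model
listens in the dips and its ratio exceeds the long-term one, increasingly so
with modulation depth.

### The short-term/long-term offset for stationary maskers

One property deserves honesty up front: for *stationary* maskers the
short-term model does **not** converge exactly to the long-term model. With
frozen long-term target statistics, the per-frame better-ear ratio averages
$10\log_{10}$ of 24-ms band powers that are approximately
$\chi^2_k$-distributed with $k \approx 2 B T \approx 3\text{–}10$ degrees of
freedom, and $E[\log(\chi^2_k / k)] < 0$; the dB-domain frame average is
therefore higher than the long-term ratio by roughly 1–2 dB (plus a smaller
term from short-window coherence/phase estimation noise in the unmasking
component). The offset is a property of the estimator, not of the scene: it
is nearly identical across conditions and cancels in the between-condition
differences the model is built to predict. The package reports it rather
than hiding it; shrinking it would require longer frames, which would
forfeit the dip-listening sensitivity the short-time framing exists for.

### Coherence estimation

Coherence is defined as the maximum of the normalised interaural
cross-correlation within $\pm 1$ ms (ties to the smaller lag). The
implementation evaluates the *magnitude of the complex (analytic-signal)
cross-correlation* on a 0.25-ms lag grid. For narrowband gammatone outputs
this envelope maximum equals the sample-wise correlation maximum whenever a
carrier cycle fits the search window, and it avoids the failure mode of
sampling a rapidly oscillating real correlation on a coarse grid at high
centre frequencies. Per-band ITDs reported by `cue_profile()` do use the
sample-wise real correlation at full lag resolution, but only for bands
below 1.5 kHz, where fine-structure ITDs are unambiguous; the summary ITD
is an energy-weighted median. Sign conventions: azimuth is 0° ahead,
positive clockwise (to the listener's right); a positive ITD means the left
ear lags (source on the right); ILD is left level minus right level.

## The synthetic scene stage

The generator emulates the study conditions the model is meant for: a
sound-treated room with T30 of 0.2 s, the listener at the centre of a
1.3-m loudspeaker ring, target ahead (0°) and three maskers either at +90°,
−90° and 180° (*separated*) or all from the frontal loudspeaker
(*collocated*), maskers fixed at a common reference level (−25 dBFS summed,
standing in for 65 dB (A)) with equal A-weighted power per masker.

* **BRIRs** (`simulate_brir()`): image-source model with
  frequency-independent wall reflectance. Because the image-source field
  does not decay at the textbook Eyring rate (late energy is dominated by
  grazing directions with few reflections), the reflectance is calibrated
  by root-finding the Schroeder-fitted (−5 to −35 dB) T30 on the enumerated
  image set; reflections get random polarity and a small seeded time jitter
  so the dense late field stays incoherent and the rendered T30 lands
  within about ±10% of the target. Binaural cues come from a spherical-head
  stand-in: Woodworth ITDs ($\frac{a}{c}(\theta + \sin\theta)$, $a$ =
  8.75 cm) applied per arrival, and a first-order high-shelf shadow cut at
  the contralateral ear (corner 1.5 kHz, depth $12\sin|\theta|$ dB). This
  is deliberately crude compared with a measured head-and-torso response —
  no pinna cues, no torso reflection, no diffraction detail — but it
  produces realistic broadband ILD/ITD/coherence patterns, which is all the
  model consumes.
* **Stimuli**: stationary speech-shaped noise is produced exactly as in the
  emulated experiment — a 2048-tap FIR derived from the difference between
  a white-noise spectrum estimate and the reference spectrum, applied to
  fresh white noise. The speech-like masker multiplies that carrier with a
  lognormal envelope driven by 2–8 Hz bandpass noise, giving syllabic-rate
  modulation and near-silent gaps (over 20% of 12-ms frames fall more than
  20 dB below mean power) while preserving the long-term spectrum within
  about 1 dB per band. The "interfering talker" reference spectrum is an
  idealised long-term-average speech shape (flat to 500 Hz, −9 dB/octave
  above). The stationary target surrogate plays the role of the averaged
  target speech; `average_target()` implements the averaging operation
  itself (skip 680 ms, truncate to the shortest, RMS-match the collocated
  masker) for use with actual sentence recordings.
* **BTE transform** (`apply_bte_transform()`): zero-phase magnitude shaping
  — a −8 dB Gaussian-in-log-frequency notch at 2.5 kHz (the lost ear-canal
  resonance; the true notch shape is only known graphically, so depth,
  centre and width are configuration), +5 dB high-shelf ILD boost above
  2 kHz at the ipsilateral ear for sources with |azimuth| ≥ 45°, a mild
  high-frequency loss, flat +10 dB insertion gain — plus a fractional-delay
  phase ramp that compresses the ITD to 0.9 of its cross-correlation
  estimate. The 0.9 factor is a surrogate for a change reported only
  qualitatively ("slightly reduced") and is configurable. In aided scenes
  all loudspeaker feeds are attenuated by 10 dB so the presentation level
  stays approximately constant.
* **Conditioning** (`condition_brirs()`): responses truncated to 300 ms; the
  first 3.85 ms of the frontal response (direct sound) filtered with the
  target's long-term magnitude spectrum, and a single scalar applied to the
  right-ear channel of the whole set so the two ears' filtered direct-sound
  RMS match.

## The simulated experiment

`run_track()` reproduces the adaptive procedure: 1-up-1-down sentence-level
staircase (step 2 dB by default — the step is not fixed by the emulated
procedure), terminating at the first trial from 16 on at which the standard
error of the threshold estimate drops below 0.8 dB, or at 32 trials. The
published procedure implies a model-based estimator without printing one;
we use a maximum-likelihood fit of a fixed-slope logistic with the SE from
the likelihood curvature, and keep the classical mean-of-reversals as a
cross-check field. Synthetic listeners are logistic responders
(`psychometric_listener()`, slope in probability per dB at midpoint, lapse
rate optional); linking simulation to model, a listener's true SRT in a
condition is a per-listener constant minus that condition's binaural ratio.
Sentence-level scoring only — morpheme scoring would require lexical
content the synthetic stimuli do not have.

`run_matrix()` orchestrates the eight-condition matrix (stationary |
modulated masker × separated | collocated × aided | unaided), reusing one
seeded set of maskers across arms so that aided-vs-unaided differences
reflect the BTE transform alone, and returns per-condition ratios with
BE/BU components, derived SRM and hearing-aid-disadvantage tables, optional
simulated-listener SRTs, and an MD5 hash of the configuration for
provenance. With the transform bypassed (`bte = NULL`) the aided arm
differs only by the playback attenuation, which cancels exactly in the
ratio — a useful end-to-end identity check.

## Numerical choices and problem sizes

* Default sampling rate 44.1 kHz everywhere; mixing rates is an error,
  never a silent resample.
* The filterbank is a cascade of four complex one-pole resonators per band
  (magnitude-normalised at centre); band phase alignment is not attempted
  because all statistics are per band.
* Frames that do not fill the 24-ms window are discarded; frames with zero
  power at both ears are flagged undefined and resolved by the consumers
  (better-ear → ceiling, unmasking → 0).
* Degenerate inputs error early: silent targets, empty signals, negative
  step sizes, listeners outside the room, BRIR sets without a frontal
  response, double application of the BTE transform.
* The test-suite and acceptance runs use 20–40 s of masker per condition
  for matrix-level checks and 120 s for the single stationary-limit
  comparison, with 200–500 staircase repetitions; these sizes give
  sampling noise well under the tolerances asserted. The model default
  (`masker_duration = 120` s) matches the emulated analysis.

## What passing tests do and do not show

The synthetic stage reproduces the *geometry and cue structure* of the
emulated experiment, not its acoustics in detail: no measured HRTFs, no
pinna or torso cues, no real speech (hence no informational masking, which
the model does not account for anyway), and a head model that is only
qualitatively correct above a few kHz. Green tests therefore demonstrate
that the model machinery is correct (closed forms, guards, invariances,
sign conventions), that the generators meet their design targets (spectrum
match, T30, ITD/ILD cues, staircase statistics), and that the end-to-end
pipeline reproduces the qualitative pattern of interest — positive
hearing-aid disadvantage for separated maskers, near-zero for collocated,
spatial release that shrinks when aided, an unmasking share of the release
of about 1–1.5 dB. They do not certify quantitative agreement with any
particular listener cohort or measured room.
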