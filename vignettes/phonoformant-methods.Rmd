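---
title: "Methods: formant entropy of heart sounds for PAH screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formant entropy of heart sounds for PAH screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoformant)
```

## The model

Pulmonary artery hypertension (PAH) — mean pulmonary artery pressure
(mPAp) ≥ 25 mmHg with a wedge/left-atrial pressure ≤ 15 mmHg at rest —
is hypothesized to add a *vowel-like* tonal component to heart sounds
recorded over the pulmonary auscultation area: the hypertensive pulmonary
circulation vibrates in a sustained, ordered way, much as vocal cords do.
`phonoformant` operationalizes that hypothesis with tools borrowed from
speech analysis:

1. **Framing.** Each mono recording is peak-normalized, resampled to
   8 kHz, and cut into non-overlapping 32-ms frames (256 samples).
2. **LPC formant tracking.** An 8th-order autocorrelation-method linear
   predictor is fitted per frame (Levinson–Durbin on a Hamming-tapered
   frame). Conjugate pole pairs of the all-pole model are candidate
   resonances; each contributes a frequency (pole angle) and an amplitude
   (all-pole envelope `gain / |A(e^{iω})|` at that frequency). The four
   strongest resonances, sorted ascending in frequency, are the frame's
   four formants. Fewer than four resonances yield explicit absent
   markers, never fabricated values.
3. **Sine-wave replica.** Each formant trajectory is resynthesized as one
   time-varying sinusoid: frequency and amplitude linearly interpolated
   between frame centers, phase accumulated as the cumulative sum of
   instantaneous frequency (hence continuous), silence in frames where
   the formant is absent. The replica deliberately discards everything
   except the formant trajectories.
4. **Entropy feature.** For formant *f*'s replica the magnitude STFT *S*
   is computed and the feature is
   `E = Σ_i Σ_bins log(S²_{f,i} + ε)` over the frames *i* of a segment.
   Because `log` is concave, a fixed budget of spectral power spread
   uniformly maximizes `E`, while power concentrated in few bins (an
   ordered, vowel-like spectrum) leaves most bins at the floor `ε` and
   drives `E` down. *Low entropy = ordered pattern.* An energy feature
   (`Σ S²`) and a narrow-band relative-power comparator (21–22 Hz band
   power fraction) are provided alongside.
5. **Cohort statistics.** Subjects are grouped by the hemodynamic rule
   above. For each of the 4 sites × 4 formants a pooled-variance
   two-sample t-test compares groups on the whole-recording feature; the
   cell with the smallest raw p identifies the informative site/formant.
   At that cell, window lengths L = 1…20 s are swept: the feature is
   averaged over the `floor(duration/L)` disjoint segments of length L,
   tested per length, and Holm–Bonferroni-corrected across the sweep
   family; the optimum is the argmin corrected p.
6. **Classification.** A one-dimensional equal-variance Gaussian LDA on
   the selected feature, evaluated by leave-one-out cross-validation,
   yields sensitivity `100·TP/(TP+FN)` and specificity `100·TN/(TN+FP)`.
7. **Power analysis.** The per-group sample size for a two-sided test is
   `n = 2(z_{1−α/2} + z_{power})² σ²/Δ²` (normal approximation, default)
   or the noncentral-t inversion (`method = "t"`), which is typically one
   subject larger.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| analysis rate | 8000 | Hz | standard speech-analysis rate; fixes the 256-sample frame |
| frame length | 0.032 | s | short enough for quasi-stationarity of heart sounds |
| LPC order | 8 | – | four pole pairs = four formants |
| pole radius floor | 0.7 | – | excludes broad-bandwidth noise poles from the formant list |
| taper | Hamming | – | un-tapered autocorrelation LPC is edge-biased |
| pre-emphasis | none | – | heart sounds are low-frequency dominant, unlike speech |
| STFT window / hop | 0.032 / 50% | s | mirrors the analysis framing; no parameters are stated for the original, so these are declared and echoed in every manifest |
| entropy floor ε | 1e-12 × max(S²) | – | keeps silent replica frames finite; computed from the whole spectrogram so entropy stays additive over partitions |
| α | 0.05 | – | conventional two-sided level |
| window grid | 1–20 | s | the sweep family; Holm-corrected as 20 tests |
| LDA priors | empirical | – | class frequencies (35/60, 25/60 on default cohorts); `"equal"` is a switch since the original choice is unstated |

## Interpretive and numerical choices

* **The entropy sum.** The feature's defining sum "over the segment
  length" is read as running over the STFT time frames of the segment
  *and* over frequency bins — the only reading that is well-defined on a
  two-dimensional spectrogram. It is isolated in `entropy_feature()` so
  a frequency-marginalized variant could be swapped in. The log base is
  natural; an unstated base would only scale all features by a constant,
  which every downstream test and classifier is invariant to.
* **"Strongest coefficients" as resonances.** Selecting "coefficients
  with the highest magnitudes" is not a standard operation on raw LPC
  coefficients; the standard formant-estimation reading — root-finding on
  the prediction polynomial, ranking candidate resonances by envelope
  amplitude — is adopted. Whether the original ranked by coefficient
  magnitude, pole radius, or envelope amplitude is undeterminable; the
  envelope rule is this package's declared convention.
* **Pooled t.** The pooled-variance Student form (not Welch) reproduces
  the printed clinical-table p-values and is the default everywhere;
  `var_equal = FALSE` switches to Welch.
* **Resampling.** Fourier-domain resampling (DFT zero-pad/truncate)
  rather than a polyphase filter bank: exact band-limited interpolation
  under periodic extension, no aliasing, no filter-design dependency.
  Verified by FFT-peak and round-trip oracles.
* **Ties and degenerates.** A case exactly on the LDA threshold is
  called normal (conservative screening default). Constant/silent frames
  are skipped with a counted absent row; a trailing partial frame or
  segment is discarded, never zero-padded.
* **Power formula discrepancy.** With the reference inputs
  (means 4.75e5 / 4.56e5, sd 9.85e3, α = 0.05, power 0.90) the normal
  approximation gives n = 6 per group; the noncentral-t inversion gives
  7. Both are offered; the normal form is the default because it matches
  the published analysis.

## What the synthetic cohort emulates — and what it does not

`synth_cohort()` generates the stated world of the target study design:
35 normal + 25 PAH subjects, 20-s mono recordings at 4000 Hz from four
sites (apex, 2LICS, 2RICS, 4LICS), mPAp drawn uniformly in 5–24 /
25–93 mmHg, wedge pressure < 15 mmHg for all.

Each recording is a train of Gaussian-enveloped S1 (30–45 Hz) and S2
(55–75 Hz) bursts at a subject heart rate of 70–130 beats/min, plus 5%
broadband sensor noise. Every recording also carries a three-harmonic
stack on 300 Hz whose RMS is 25% of the base signal and whose higher
harmonics are weak (relative amplitudes 1 / 0.2 / 0.08) so the pattern is
dominated by its fundamental, as the reported vowel-like phenomenon is.
The *only* group difference is order: PAH recordings at the 2LICS carry
the stack with slow (2 Hz bandwidth), small (2%) frequency drift and
gentle amplitude modulation; all other recordings carry the identical-
power stack with fast (20 Hz), heavy (35% log-scale) jitter and deep
amplitude scrambling. Stability — not amplitude — encodes the contrast,
so the entropy feature responds to spectral order alone, and the energy
feature does not trivially separate the groups.

A first design iteration gave normal subjects an equal-power band-noise
component instead; it was abandoned (before any acceptance threshold was
set) because absent-formant bookkeeping, not spectral order, then
dominated the entropy contrast. The final design keeps both groups'
formant slots populated symmetrically.

A green end-to-end test therefore establishes that the pipeline recovers
a planted ordered-vs-disordered contrast at the planted site and formant
under realistic carrier signals — it does **not** establish clinical
performance, hemodynamic fidelity, murmur robustness, or anything about
real stethoscope noise floors. The published patient-cohort p-values are
not reproducible without the original recordings and are not claimed.

## Scaling of the stochastic acceptance checks

The end-to-end recovery check runs the full 60-subject, four-site,
20-s-recording world over five seeds (a few minutes of CPU). The
null-calibration check ("no corrected significance under
`signature_strength = 0`") needs ≥ 200 replicates of the 20-length sweep;
200 audio cohorts would take hours, so those replicates run at the
feature level with per-subject cross-length correlation — legitimate
because Holm's family-wise guarantee is distribution-free — while a
single audio-level null cohort is additionally run through the whole
pipeline as a fixed-seed smoke check.

## Known limitations

* The formant tracker applies no continuity constraint across frames
  (no Viterbi smoothing); rapid slot switching between burst-driven and
  tonal resonances is visible in the tracks and is part of the measured
  signal.
* The entropy feature conflates spectral concentration with replica
  silence: a formant absent for many frames contributes floor-level
  terms. The synthetic world is designed so this bookkeeping is
  group-symmetric; on real data with asymmetric dropout the feature
  would need care.
* WAV support covers uncompressed PCM and IEEE float, mono only.
* The window sweep reuses one spectrogram per recording, so segment
  boundaries are quantized to the STFT hop (16 ms).
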