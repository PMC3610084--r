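---
title: "Quantifying speech motor function with the Speech Modulation Spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying speech motor function with the Speech Modulation Spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmod)
```

## The model

Speech carries information at several timescales at once. Vowel-like,
syllabic events modulate the amplitude envelope slowly (hundreds of
milliseconds); consonant blends and vowel transitions act at tens of
milliseconds; plosive-like articulatory events are faster still. A
child's ability to produce sound at progressively shorter timescales
tracks the maturation of speech motor control, which makes a
timescale-resolved summary of vocalizations a candidate speech-motor
metric — in particular for toddlers with autism spectrum disorder
(ASD), whose vocal repertoire often contains atypical fast transients.

`speechmod` quantifies this with the **Speech Modulation Spectrum**.
For a recording $x(t)$ we compute a spectrogram $S(f, t)$, then take a
two-dimensional Fourier transform of (mean-removed) fixed-length
chunks of $S$ and average the squared magnitude across chunks. The
result is a power distribution over

* spectral modulation $\omega_f$ (cycles/kHz): density of structure
  across the frequency axis (harmonic spacing, formant structure), and
* temporal modulation $\omega_t$ (Hz): rate of energy fluctuation over
  time at a fixed frequency.

Normalized to unit sum, the modulation spectrum is read as a
probability distribution over spectro-temporal modulations. The
package's core feature, the **contour area**, is the size (in bins) of
the smallest set of modulation bins whose cumulative power reaches
99.9% of the total — i.e. the support needed to account for
essentially all modulation energy. The contour is then partitioned
along the temporal-modulation axis into three bands:

| band | range (Hz) | articulatory interpretation |
|------|-----------|------------------------------|
| SR   | 0–10      | syllabic rhythm, supra-segmental envelope |
| FT   | 10–50     | formant transitions, consonant blends |
| POA  | 50–100    | place-of-articulation-scale, plosive-like transients |

Band areas always sum to the total contour area (the bands tile
$[0, 100]$ Hz; intervals are half-open except the last). A band is
"present" when it contributes at least one contour bin.

These particular band edges follow the operational partition statement
of the developmental literature this measure comes from; descriptive
passages in that literature also mention 2–10, 20–40 and 25–40 Hz for
the same constructs, but only the 0–10/10–50/50–100 partition defines
areas that sum to the total, so it is the default here. The edges are
configurable (`default_bands()`).

## Numerical choices

**Spectrogram.** 25 ms Gaussian window (sd = length/6), 2 ms hop,
frequencies up to 8 kHz, log (dB) magnitude floored 80 dB below the
per-file maximum. The 2 ms hop puts the temporal-modulation Nyquist at
250 Hz, comfortably above the 100 Hz upper band edge. The FFT length
is 1024 at 22.05 kHz (frequency step ≈ 21.5 Hz), which places the
spectral-modulation Nyquist near 23 cycles/kHz. Child vocalization has
fundamental frequencies near 300 Hz, i.e. harmonic structure at about
3.3 cycles/kHz, so the default contour domain $|\omega_f| \le 20$
cycles/kHz covers the finest spectral structure these recordings
contain with a wide margin, at a fraction of the cost of a finer grid.

**Chunking.** The 2-D transform is taken over 1 s chunks with 50%
overlap and power-averaged. Fixed chunking makes the modulation grid —
1 Hz resolution in $\omega_t$ — identical for every participant
regardless of recording length, which is what makes contour *bin
counts* comparable across participants.

**Contour extraction.** Bins are accumulated in decreasing order of
power until the energy fraction is reached; this minimal-count set is
the literal "number of spectro-temporal modulations" reading of the
contour, rather than a smoothed geometric isocontour (which we treat
as visualization). Ties are broken toward lower $|\omega_t|$, then
lower $|\omega_f|$, so results are deterministic. The DC bin
$(\omega_f = 0, \omega_t = 0)$ encodes overall level, not
articulation, and is excluded. Only the $\omega_t \ge 0$ half plane is
analysed; the underlying transform of a real spectrogram is Hermitian,
so the other half is redundant (the package verifies
$P(\omega_f, \omega_t) = P(-\omega_f, -\omega_t)$ and Parseval energy
conservation as invariants).

**Degenerate inputs.** Silent or empty recordings raise a
degenerate-input error rather than returning zero areas; an all-zero
modulation domain cannot support a 99.9% contour.

## Vocalization counting

A vocalization is a continuous run of vocal activity with no internal
pause longer than 300 ms. Activity is detected per 10 ms frame by an
energy rule: a frame is active when its RMS level exceeds the adaptive
noise floor (5th percentile of frame levels) by 15 dB, or exceeds an
absolute −25 dBFS level (the absolute rule keeps uniformly loud input
active; with a constant signal the adaptive floor equals the signal
level). Active runs separated by gaps of at most 300 ms are merged;
the boundary is inclusive — a gap of exactly 300 ms does not split.
Counts are normalized to vocalizations per minute. The original
procedure this emulates used two human listeners; the energy detector
is an algorithmic stand-in, and a second parameter set can emulate a
second rater if desired.

## The synthetic cohort generator

No audio from the motivating study is available, so the package ships
a generator whose outputs exercise every stage end-to-end.

A vocalization is synthesized as a train of utterances: a 300 Hz
harmonic carrier shaped by three vowel-like formant resonances
(700/1800/3200 Hz), amplitude-modulated by a raised-cosine syllable
envelope (rates around 3.5–5 Hz), with a linear second-formant glide
at each syllable onset (transition-like component, default 40 ms) and
short Hann-windowed noise bursts (plosive-like transients, default
10 ms). Each knob maps onto one modulation band: the envelope rate
drives SR, the glides drive FT, the bursts drive POA.

Cohorts follow three group profiles (ASD n = 39, TD n = 26, DD
n = 20 by default) whose behavioral-score distributions — Mullen
T-scores and composite, Vineland V-scores and composite, ADOS totals —
are Gaussians with the published group means and SDs, truncated to the
published ranges so scales stay legal (`cohort_reference()` holds
these numbers). VIQ is the mean of the two Mullen language T-scores.

The **fast-modulation gain** is the generator's effect-size knob: it
multiplies transient energy, implemented as a joint multiplier on
burst amplitude (base 0.06 relative to the voiced carrier) and burst
rate (base 3/s). Amplitude alone would be compressed by the log
spectrogram (a 3× gain is only +9.5 dB), so event rate carries part of
the energy increase, mirroring the interpretation that atypical
repertoires contain *more* fast transient events. Per participant the
gain is lognormal (long-tailed, mimicking the high heterogeneity of
ASD data): ASD median 3.0 with `sdlog` 0.6 and a −0.6 latent coupling
to VIQ (fast-transient energy concentrates in low-verbal
participants); TD and DD have median 1.0 with `sdlog` 0.3. Background
noise defaults to 60 dB SNR: below ≈45 dB, dB-scale noise fluctuations
spread the 99.9% contour over nearly the entire modulation plane and
the measure saturates. Vocalization rates are 11/min (TD), 7.5/min
(DD) and 6/min (ASD) — ordered as in the motivating cohort, with the
specific values being design choices. Everything is deterministic
given the cohort seed.

What the generator does *not* emulate: phonetically realistic child
speech, prosody, recording-channel variation, adult-speech bleed, or
realistic naturalistic noise. One visible consequence: because log
spectrograms give every voiced utterance some fast edge energy, all
three bands are present for essentially every synthetic participant,
so presence percentages sit at 100% and the expected presence decline
from SR to POA appears only as equalities. Passing tests on this
cohort therefore demonstrate that the pipeline recovers structure the
generator puts in — not that real toddler recordings would show the
same effect sizes.

`inject_correlation()` imposes a target feature–score correlation by
regenerating the score as a linear Gaussian coupling to the
standardized feature (preserving the score's sample mean and SD). The
coupling is linear rather than rank-based so that the population
Pearson correlation is exactly the requested $\rho$, with $\rho = 1$
reproducing $r = 1$ to float precision.

## Statistics

The battery mirrors a developmental group-comparison study: a
Kruskal–Wallis test across the three timescales (with Tukey
comparisons on the rank scale — the rank transform makes the
nonstandard "Tukey after Kruskal–Wallis" pairing coherent),
Kruskal–Wallis across groups per band, one-way ANOVAs comparing
low-VIQ-ASD/TD/DD and high-VIQ-ASD/TD/DD per band (the ASD group is
split at its mean VIQ; values exactly at the cutoff go to the low
group, since "high" is defined strictly above), protected Fisher LSD
for the POA comparison, Tukey HSD for the vocalization-rate ANOVA,
per-group Pearson correlation tables with conventional stars,
descriptive statistics with a Shapiro–Wilk normality flag, and
presence percentages per band. All tests are two-sided at
$\alpha = 0.05$.

`anova_from_summary()` reconstructs a one-way F from printed
per-group means, SDs and sizes (between-group SS from means and sizes,
within-group SS from SDs); it equals `one_way_anova()` on any raw data
realizing those summaries exactly, which the tests verify by
construction.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_spec(
  profiles = default_profiles(n = c(ASD = 12, TD = 10, DD = 10)),
  recording_duration = 10, seed = 1))
feats <- extract_cohort_features(coh)
presence_percentages(feats)

sp <- split_by_viq(feats[feats$group == "ASD", ])
one_way_anova(list(LVIQ_ASD = sp$lviq$poa_area,
                   TD = feats$poa_area[feats$group == "TD"],
                   DD = feats$poa_area[feats$group == "DD"]))
```

## Problem sizes used by the test suite

The shipped tests scale the simulations to desk size as a deliberate
design: the null-calibration check uses 1000 score-only cohorts
(3 × 10 participants); the effect-recovery check uses 100 audio
cohorts of 12/8/8 participants with 3 s recordings (a pilot power
analysis at the generator's planned effect size showed ≈93% replicate
significance at this size); the presence check uses 8/8/8 at 4 s; the
correlation-recovery check uses n = 500 score-only records with the
POA area represented by its deterministic gain response. The
acceptance script analyses a 12/10/10 cohort at 10 s per participant.
Full-scale cohorts (39/26/20 at 2–5 min) run with the same code and
default configuration, only longer.

## Known limitations

* The contour area is a bin count, so it depends on the modulation
  grid; comparisons are only meaningful within one configuration.
* The energy activity detector does not distinguish speech from
  non-speech vocal sounds (cries, laughs) or from residual
  non-excised adult speech.
* Log-scale spectrograms make band *presence* nearly universal;
  band *areas* carry the discriminative signal.
* Whether the motivating study low-pass filtered or denoised its
  samples is unstated; the package applies no denoising.
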