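# speechmod

Articulatory features from the Speech Modulation Spectrum — an R
package for quantifying speech motor function in child vocalization
recordings, with a synthetic toddler-vocalization cohort generator and
the group-comparison statistics used in developmental speech-motor
studies.

## The problem

Toddlers at risk for autism spectrum disorder (ASD) often show
atypical vocalization patterns before reliable language measures are
available. One quantitative angle is *speech motor function*: the
ability to produce sound at progressively shorter articulatory
timescales matures with speech motor control, so a timescale-resolved
summary of a child's vocalizations can serve as a speech-motor metric
and candidate early risk indicator. This package implements that
analysis for researchers working with naturalistic child recordings
(and, because clinical audio is rarely shareable, ships a synthetic
cohort generator so the full pipeline is testable end to end).

## The measure

For a recording, compute a spectrogram `S(f, t)`, then take the 2-D
Fourier transform of mean-removed 1 s chunks of `S` and power-average:
the **Speech Modulation Spectrum**, a distribution over spectral
modulation ω_f (cycles/kHz) and temporal modulation ω_t (Hz).
Normalized to unit sum, its **contour area** is the number of
modulation bins in the smallest set covering 99.9% of the energy. The
contour is partitioned along ω_t into three articulatory bands:

* **SR** (syllabic rhythm), 0–10 Hz
* **FT** (formant transitions), 10–50 Hz
* **POA** (place of articulation), 50–100 Hz

Band areas sum to the total contour area; a band is *present* when it
holds at least one contour bin. The package also counts
**vocalizations** (continuous vocal activity with no pause > 300 ms,
normalized per minute) and provides the statistical battery:
Kruskal–Wallis, one-way ANOVA (including reconstruction of F from
printed mean/SD/n summaries), Tukey and protected Fisher LSD post-hoc
tests, per-group Pearson correlation tables, descriptive statistics
with normality flags, and VIQ-based subgroup splits.

## Worked example

```r
library(speechmod)

coh <- generate_cohort(cohort_spec(
  profiles = default_profiles(n = c(ASD = 12, TD = 10, DD = 10)),
  recording_duration = 10, seed = 1))
feats <- extract_cohort_features(coh)

aggregate(cbind(sr_area, ft_area, poa_area) ~ group, feats,
          function(v) round(mean(v)))
#>   group sr_area ft_area poa_area
#> 1   ASD    2071    4484     2574
#> 2    DD    1910    3483     1338
#> 3    TD    1990    3164     1126

sp <- split_by_viq(feats[feats$group == "ASD", ])
one_way_anova(list(LVIQ_ASD = sp$lviq$poa_area,
                   TD = feats$poa_area[feats$group == "TD"],
                   DD = feats$poa_area[feats$group == "DD"]))
#> <one-way ANOVA: statistic = 22.6, df = 2, 23, p = 3.725e-06>
```

The ASD-like group — whose generator profile carries an elevated,
long-tailed fast-modulation gain concentrated in low-VIQ participants
— shows the largest POA (fast-timescale) contour area, and the
low-VIQ-ASD vs TD vs DD ANOVA detects the group effect.

Reference cohort characteristics (group sizes, sex counts, behavioral
score summaries) are bundled for parameterizing the simulator and for
summary-level statistics:

```r
ref <- cohort_reference()
chi_square_independence(ref$gender_counts)
#> <chi-squared independence: statistic = 1.072, df = 2, p = 0.5852>

s <- ref$summaries[ref$summaries$scale == "mullen_el", ]
anova_from_summary(s$mean, s$sd, s$n)
#> <one-way ANOVA (from summaries): statistic = 47.16, df = 2, 82, p = 2.336e-14>
```

Real recordings are analysed the same way via the pipeline's
`audio-dir` mode: a manifest CSV (`id, wav, annotation, group, ...`)
points at 16-bit PCM WAV files and optional exclusion-interval CSVs
(adult speech, environmental noise); see `?run_pipeline`.

## Documentation

The methods vignette (`vignettes/articulatory-features.Rmd`) describes
the model, the numerical choices (window, chunking, contour
tie-breaks, degenerate inputs), what the synthetic generator does and
does not emulate, and known limitations.
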