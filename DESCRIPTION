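Package: speechmod
Title: Articulatory Features from the Speech Modulation Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies speech motor function in child vocalization
    recordings via the Speech Modulation Spectrum: a spectrogram is
    decomposed by a two-dimensional Fourier transform into spectral and
    temporal modulation frequencies, and the minimal set of modulation
    bins covering 99.9 percent of the modulation energy (the "contour
    area") is summarized in three temporal-modulation bands associated
    with syllabic rhythm (0-10 Hz), formant transitions (10-50 Hz), and
    place of articulation (50-100 Hz).  Also provides pause-based
    vocalization counting (300 ms rule), a synthetic toddler-vocalization
    cohort generator with group-structured behavioral scores for
    end-to-end testing, and the group-comparison and correlation
    statistics used in developmental speech-motor studies
    (Kruskal-Wallis, one-way ANOVA including reconstruction from summary
    statistics, Tukey and Fisher LSD post-hoc tests, Pearson correlation
    tables, descriptive statistics with normality flags).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
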