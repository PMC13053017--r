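Package: promkin
Title: Acoustic Prominence and Co-Speech Hand Movement Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal coupling of co-speech hand
    movements and spoken lexical stress. Nominates the acoustically most
    prominent syllable of a spoken word from a weighted composite of
    z-normalized duration, peak fundamental frequency and peak amplitude-
    envelope cues; detects the maximum-extension apex of a biphasic hand
    movement from vertical pose-tracking time series; computes gesture-speech
    asynchrony; and fits mixed-effects models of asynchrony, intensity and
    production accuracy across stress-matching and stress-mismatching cognate
    items. A synthetic-study generator emits audio, Praat TextGrid syllable
    tiers and pose tracks with known ground truth so the whole pipeline can be
    exercised and validated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
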