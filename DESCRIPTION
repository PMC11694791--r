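Package: infrakit
Title: Spectral and Behavioral Analysis of Infradian Locomotor Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of locomotor rhythms slower than a
    day (infradian, 27-96 hours) alongside the circadian rhythm in rodent
    actigraphy. Provides Lomb-Scargle periodograms with analytic or
    permutation significance thresholds, the percent amplitude-spectral-density
    (%ASD) partition of significant power into circadian and infradian bands,
    the trough-anchored (Tro) power split for clock-deficient animals,
    analytic Morse/Morlet continuous wavelet scalograms with ridge tracking
    and scale-averaged band power, immobility-based sleep scoring of
    passive-infrared records with active/inactive day labeling at 48-hour
    cycles, open-field path metrics (total distance and the fractal spatial-d
    straightness statistic), actogram matrices including modulo plotting, and
    a two-oscillator synthetic generator (circadian plus an emerging
    dopamine-oscillator-like component with period drift, relative
    coordination, and beating) so every stage can be exercised without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
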