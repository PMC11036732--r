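Package: gtrflex
Title: Video-Based Quantification of the Glabellar Tap Reflex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying the glabellar tap reflex (GTR) from
    high-framerate facial video. Reduces a 468-point facial-landmark stream
    and the frame raster to one-dimensional tapping (mean blue intensity in
    a glabellar region of interest) and blinking (inverted non-zero eye
    pixel count) signals, conditions them (running-percentile baseline
    removal, zero-phase low-pass filtering), detects tap and blink events
    by peak prominence, measures blink duration as width at half
    prominence, classifies blinks as reflex or non-reflex using a fixed
    latency window around each tap, and summarises cohorts with per-tap
    group tables, Shapiro-Wilk normality screening with a transformation
    ladder, and exact Wilcoxon rank-sum comparisons. A seeded synthetic
    session generator produces ground-truthed schedules, signals and
    rendered frame plus landmark streams so every stage is testable
    without patient video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    zoo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
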