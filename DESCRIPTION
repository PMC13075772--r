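Package: audthal
Title: Behavioral and Neural Analysis of Pure-Tone and Narrowband-Noise
    Auditory Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for go/no-go auditory detection behavior and
    spike-sorted auditory thalamus recordings obtained with pure-tone (PT)
    and narrowband-noise (NBN) stimulus sets. Provides signal-detection
    scoring of lever-release sessions (hit/miss/false-alarm/correct-
    rejection/abort labels, d-prime), log-normal rate-level fitting with
    C50 and characteristic-frequency extraction, PSTH latency and
    interspike-interval decay-constant estimation, a trial-wise
    two-alternative frequency-discriminability statistic, pseudopopulation
    frequency decoding with linear support-vector classifiers, tonotopic
    gradient regression, and a seeded synthetic-data generator emulating
    the statistical structure of such experiments for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    lhs,
    minpack.lm,
    signal,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
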