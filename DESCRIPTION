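Package: lsfgpwf
Title: Pulse Waveform Analysis of Ocular Blood Flow from Laser Speckle
    Flowgraphy
Version: 0.1.0
Authors@R:
    person("LSFG", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pulsatile ocular blood flow recorded by
    laser speckle flowgraphy (LSFG) at the optic nerve head. Mean blur
    rate (MBR) frame sequences are cropped to a region of interest, split
    into vessel and tissue compartments, synchronized to the cardiac
    cycle, and summarised by pulse-waveform (PWF) parameters: blowout
    score and time, rising and falling rates, S1/S2 areas from a
    second-order trend fit, flow acceleration index, acceleration time
    index, and resistive index. Includes a seeded synthetic-data
    generator for pulsatile acquisitions and longitudinal carotid
    stenosis studies, a combined neurological and behavioural assessment
    (NBA) scoring rubric, and a longitudinal statistics layer with
    baseline normalization, repeated-measures testing, correlation,
    multivariate regression, and classification of vessel-resistance
    versus vessel-elasticity phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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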