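Package: msbiotyper
Title: Strain Differentiation by Low-Resolution Mass-Spectrometry Biotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemically differentiating microbial strains from
    unit-resolution electrospray mass-spectrometry peak lists. Implements
    relative-abundance and recurrence ion filtering, common and distinctive
    ion profiling across culture media and incubation periods, conversion of
    [M+H]+ / [M-H]- adduct ions to neutral nominal masses with matching
    against a compound library, combinatorial neutral-loss annotation of
    MS/MS spectra with elemental consistency checks, an integrated biotyping
    report, and a seeded synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
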