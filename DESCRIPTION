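Package: kanjinet
Title: Dual-Pathway Connectionist Model of Japanese Exception-Word Reading
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates reading aloud of two-character (kanji-like) words with a
    continuous-time recurrent sigmoid network comprising visual, phonetic input,
    semantic and phonetic output systems linked through hidden layers. Provides a
    synthetic quasiregular lexicon generator with controlled consistency and
    typicality structure (friends/neighbors ratios), a developmental training
    curriculum (preliteracy, weight freezing, literacy with drilling),
    semantic-layer lesion experiments approximating anterior temporal lobe
    disruption, nearest-neighbor phonological decoding with a surface/semantic
    error taxonomy, and repeated-measures analysis of the lesion-by-typicality
    interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
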