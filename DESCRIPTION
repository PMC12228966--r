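Package: utrforge
Title: Generative Design and Optimization of 5' UTR Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic human-like 5' untranslated region (UTR)
    sequences with a Wasserstein generative adversarial network trained with a
    gradient penalty, and tunes the generated sequences by gradient ascent on
    the generator's latent input against any differentiable scorer: UTR-only
    scorers (ribosome load / translation efficiency style) or gene-window
    scorers that embed the UTR at the transcription start site of a fixed
    10.5 kb window before scoring. Includes the sequence codec (5-channel
    one-hot with a padding token), built-in analytically tractable scorers, an
    adapter contract for external predictors, a sequence-set evaluation suite
    (nearest-neighbour Levenshtein and k-mer distances, GC content, minimum
    free energy via ViennaRNA, uORF / G-quadruplex / Kozak motif scans), and a
    synthetic-data generator so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
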