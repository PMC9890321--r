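Package: vocalcomb
Title: Multi-Level Combinatorial Analysis of Animal Vocal Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying multi-level combinatoriality in animal
    vocal repertoires from annotated field recordings. Reads Praat TextGrid
    annotations organised on three tiers (segment, call, combination) together
    with their WAV recordings, standardises each vocal unit into a 64x64
    log-Mel spectrogram, projects spectrogram datasets into a two-dimensional
    latent space (UMAP) and scores how well predictors such as hand label,
    caller identity, group, site or sex explain the layout (silhouette score
    with a permuted-label Kruskal-Wallis test). First-order forward transition
    probabilities between vocal units are tested against frequency-preserving
    randomised-assignment null distributions by Monte-Carlo simulation, at both
    the within-call (segment) and between-call (call combination) levels. A
    seeded synthetic corpus generator renders WAV + TextGrid corpora with known
    two-level transition structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    signal,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
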