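Package: perplexityBOLD
Title: Stream-Wise Perplexity Regressors for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains trigram (second-order Markov) language models over
    lexical, part-of-speech, and phonological annotation streams of a
    continuous speech stimulus, derives per-word surprisal and perplexity
    covariates, and fits them as hemodynamically convolved parametric
    modulators in a voxelwise GLM with a real-versus-reversed-speech
    contrast. Group t maps are corrected by Monte-Carlo cluster-extent
    simulation calibrated to the estimated spatial smoothness, and overlap
    between streams is assessed by conjunction-null analysis. A seeded
    synthetic-data generator (Zipfian lexicon, tag-chain corpora,
    word-timed transcripts, BOLD volumes with planted effects) provides
    fully reproducible end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
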