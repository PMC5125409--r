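Package: artic
Title: Articulatory Modelling and Concatenative Visual Speech Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning multimodal speech-production recordings
    (electromagnetic articulography of the tongue plus optical motion
    capture of the face, with phone segmentations) into a compact
    articulatory model and a visual speech synthesizer.  The package
    synchronizes sensor streams recorded at different rates, estimates and
    removes rigid head motion by orthogonal Procrustes fitting, builds a
    guided principal-component articulatory model by iterative extraction
    on landmark subsets, recovers articulatory parameter trajectories by
    bounded least-squares inversion, retargets avatar key frames onto the
    articulatory parameter space, and synthesizes new utterances by
    diphone unit selection with gapless boundary processing.  A
    synthetic-data generator produces ground-truth corpora with planted
    models so that every stage of the pipeline can be validated against a
    known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
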