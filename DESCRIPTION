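Package: scfp
Title: SMILES Convolution Fingerprints and Chemical Motif Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes chemical compounds as fixed-size feature matrices built
    from their canonical SMILES strings (21 atom features and 21 SMILES
    grammar features per symbol), learns a 64-dimensional molecular
    fingerprint (SCFP) with a two-stage one-dimensional convolutional
    neural network trained by mini-batch Adam, classifies compounds
    (e.g. toxicity assays), and traces high-activation convolution filters
    back to the input substructures that drive them ("chemical motifs")
    via Z-scoring of the global-max-pooled activations and receptive-field
    traceback.  Includes a synthetic molecule generator that plants known
    substructures so the whole pipeline can be exercised and benchmarked
    without external data, readers and writers for SMILES-TSV and SDF, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    igraph,
    ChemmineOB,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
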