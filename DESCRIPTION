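Package: asdscreen
Title: Screening for Autism Spectrum Disorder from Scanned Medical Forms
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for screening children for autism spectrum disorder
    (ASD) from scanned, hand-written medical forms and their transcribed
    text. Scanned pages are de-skewed by entropy minimisation over the
    per-row black-pixel profile and de-identified by Sobel-edge marker
    detection and region blanking. Transcribed documents are embedded as
    bag-of-words, n-gram and tf-idf lexical features, latent Dirichlet
    allocation topic distributions (collapsed Gibbs sampling), and
    paragraph vectors trained with a full-softmax continuous bag-of-words
    objective (PV-DM). Class imbalance is corrected by interpolation
    upsampling between nearest positive neighbours, and classification
    uses L1- or L2-regularised squared-hinge linear support vector
    machines under stratified nested cross-validation with F2-oriented
    model selection. Synthetic form images and labelled two-class corpora
    with known ground truth make every stage testable without access to
    confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
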