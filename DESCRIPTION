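Package: hanscribe
Title: Hierarchical Attention Networks for Dementia Screening from
    Picture-Description Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies picture-description transcripts (Alzheimer's disease
    versus cognitively normal controls) with a two-level hierarchical attention
    network: a bidirectional GRU word encoder with word-level attention builds
    sentence vectors, and a bidirectional GRU sentence encoder with
    sentence-level attention builds the document vector fed to a softmax
    classifier. Ships CHAT (.cha) transcript cleaning, GloVe embedding loading,
    stratified splits and five-fold cross-validation, attention-ablation
    variants, confusion-matrix metrics, hierarchical attention-weight
    normalization with HTML heatmap reports, and a synthetic transcript
    generator that plants the lexical markers of the disease class (fillers,
    pronoun substitution, reduced content-word coverage, shorter documents) so
    the full pipeline is testable without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    stringi,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
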