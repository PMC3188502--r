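Package: dupscan
Title: Detecting Binding-Site Formation by Local Sequence Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical inference of local sequence duplication as a mode of
    transcription factor binding site formation in cis-regulatory modules.
    Implements distance-resolved sequence autocorrelation and
    similarity-information statistics with a dynamic-programming detector of
    non-overlapping similar site pairs calibrated against a first-order Markov
    null; an evolutionary likelihood model (Halpern-Bruno fitness landscapes,
    Kimura-Ohta substitution dynamics) comparing common versus independent
    descent of binding-site pairs; mixture-model quantification of the
    duplicated fraction of site pairs; binding-correlation analysis of the
    adaptive potential of duplications; and a synthetic-data generator so the
    whole pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
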