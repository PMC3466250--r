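Package: oligocap
Title: Processing and Classification of Oligo-Capped Full-Length cDNA and EST Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing paired 5'/3' Sanger reads from oligo-capped
    full-length cDNA libraries: per-read quality and vector trimming, cap-tag
    and poly(A)-tail detection, contaminant filtering, paired-read overlap
    assembly, a decision tree classifying clones into full-length coding,
    full-length noncoding, truncated-EST, walking-candidate and 5'/3'-EST
    categories, greedy identity clustering for non-redundant sets,
    polyadenylation-signal detection by hexamer precedence, homology-guided
    open-reading-frame prediction, differential gene-loss categorisation, and
    a ground-truth library simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
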