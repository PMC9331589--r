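Package: tistr
Title: Tandem Repeats Upstream of Translation Initiation Sites and TIS
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines exact tandem repeats (TRs) in the 120-bp sequence
    upstream of translation initiation sites (TISs), classifies TR types
    as reference-species-specific or shared within cross-species gene
    groups, scores TIS conservation with a weighted similarity over the
    first amino-acid positions of the encoded protein, and tests whether
    reference-specific upstream TRs co-occur with diverged TISs using a
    Fisher's exact test replicated over gene-subsampled folds.  Includes
    an affine-gap global protein aligner for a complementary full-protein
    divergence check and a synthetic multi-species data generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
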