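Package: hashIBD
Title: Identity-by-Descent Detection via Locality-Sensitive Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects identity-by-descent (IBD) segments between phased
    haplotypes with a locality-sensitive hashing pipeline: the genome is cut
    into fixed-boundary slices by genetic distance, each haplotype's slice is
    shingled into hashed k-mers, minhash signatures estimate Jaccard
    similarity between slices, and banded LSH signatures propose candidate
    pairs that are refined and extended SNP-by-SNP into maximal IBD segments.
    Includes readers and writers for PLINK-style phased haplotype text and
    GERMLINE-compatible match files, a synthetic panel generator with planted
    ground-truth IBD and composite-individual shuffling, and an evaluation
    harness for accuracy, length-binned recovery and false-positive counting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
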