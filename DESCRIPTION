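Package: minivote
Title: Privacy-Preserving Read Alignment by MinHash Indexing and Secure
    Kmer Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-phase short-read aligner for hybrid-cloud settings. Phase
    one selects candidate alignment contigs on the trusted client with a
    MinHash locality-sensitive-hashing index of reference genome windows
    (rolling fingerprints, multiply-shift bucket hashing, contig-compressed
    buckets). Phase two scores each read/contig pair by kmer voting, which
    can be outsourced: kmers are keyed-hashed (SHA-1 with per-task rekeying),
    local repeats are masked, positions are revealed only up to shuffled
    bins, and contig kmers are sampled, so the untrusted side sees no
    sequence content, no global and no local repeat structure. Includes a
    wgsim-style read simulator with ground truth, SAM output, mapping-quality
    estimation from best and second-best voting scores, and evaluation
    utilities (Q10 percentage and Q10 error rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    dplyr,
    withr,
    yaml,
    knitr,
    rmarkdown
SystemRequirements: C++17
Config/testthat/edition: 3
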