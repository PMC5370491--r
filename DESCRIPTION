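Package: seqcontam
Title: Detection, Quantification and Correction of Cross-Contamination in
    Multi-Sample Sequencing Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing and correcting cross-sample contamination
    in multi-species sequencing projects. Provides a barcode-based screen
    for between-species contamination (read mapping to an aligned cox1
    reference panel, divergence masking, per-million prevalence accounting,
    contamination matrices), a read-count "homo-quartet" statistic for
    within-species allele leakage (error matrices and the leakage indices
    lambda and lambda-prime), a contamination-aware genotype and SNP caller
    based on a multinomial read-count mixture with a per-read contamination
    probability gamma, downstream population-genomic summaries (piS, piN,
    F_IT, Tajima's D), permutation tests linking contamination to laboratory
    metadata, and seeded simulators producing every input format with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
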