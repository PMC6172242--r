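Package: asaccess
Title: Antisense Probe Design and In Vivo RNA Accessibility Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs antisense RNA probe panels over bacterial small RNAs by
    coupling a biophysical hybridization score (partition-function unpaired
    probabilities plus duplex, target-opening and probe self-folding free
    energies) to a knowledge-gradient weighted set-cover optimizer. Quantifies
    regional in vivo accessibility from paired-end anti-termination reporter
    read lengths, classifies chaperone (Hfq) dependency of small RNAs from
    paired strain comparisons, and calls likely functional sRNA regions used
    to filter computational sRNA:mRNA target predictions. Includes a
    ground-truth synthetic data generator for the full pipeline and a
    brute-force structure-enumeration oracle for the thermodynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
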