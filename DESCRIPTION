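Package: ctdnatrack
Title: Longitudinal Circulating Tumor DNA Variant Filtering and Signature Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking somatic point mutations in plasma cell-free DNA
    across chemotherapy cycles. Implements tumor-enriched read selection by
    cfDNA fragment size, a five-condition somatic SNV filter cascade over
    paired tumor/normal pileup evidence (mutant-read and strand support,
    normal contamination, database cross-checks, local-context outlier and
    indel/mismatch rules, binomial detection power, and a recurrence-weighted
    posterior probability), trinucleotide mutation-spectrum construction with
    non-negative least-squares signature decomposition, and longitudinal
    mutation-burden, allele-frequency and survival statistics. A synthetic
    data generator produces paired tumor/normal reads with known truth
    variants, fragment-length mixtures, signature-mixture catalogs and
    multi-cycle cohorts so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    survival,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
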