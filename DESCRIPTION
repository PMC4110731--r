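Package: mirtarget
Title: miRNA Target Prediction from Whole-Gene Seed Matches and Hybridization Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA targets by scanning entire gene sequences
    (promoter, 5'UTR, CDS and 3'UTR) for four canonical seed-match types and a
    single-G:U-wobble type, weighting each site by signal-to-noise ratios
    estimated from a verified-pair corpus against a shuffled-sequence
    background, summarizing per-pair duplex hybridization and target-site
    accessibility free energies with those weights, and calling putative
    targets by dual energy cutoffs. Includes a nearest-neighbor duplex and
    constrained-folding energy engine, a synthetic corpus generator with a
    planted-site ledger, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
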