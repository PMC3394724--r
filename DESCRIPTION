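Package: divsig
Title: Selection Signature Scanning in Divergently Selected Line Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Multi-signal selection-signature analysis for pairs of lines under
    divergent artificial selection, as used to localize major loci for chicken
    abdominal fat content. Computes sliding-window allele-frequency differences
    and expected heterozygosity between two selected lines with per-chromosome
    standardization (AFD, Z_AFD, Z_lean, Z_fat), corroborates flagged regions
    with pairwise linkage disequilibrium, likelihood-based D-prime confidence
    intervals and Gabriel-rule haplotype blocks, per-line haplotype frequency
    tables with recombinant-haplotype detection, and extended haplotype
    homozygosity (EHH) decay curves. Includes a two-step GLS-LS single-SNP
    association test for additive and dominance effects with a random half-sib
    family effect, and a forward simulator of two-line divergent truncation
    selection (11 generations, 1 sire : 4 dams, 25 half-sib families per line)
    so every stage of the pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
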