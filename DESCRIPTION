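Package: cupsig
Title: Drug-Response Gene Signatures and Assay Statistics for CUP Spheroid Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a transcriptional signature of MEK-inhibitor (trametinib)
    resistance from a cancer cell-line expression/response panel (Pearson
    correlation screen, recursive feature elimination with linear support
    vector machines), classifies samples as drug-sensitive or drug-resistant
    from the sign and significance of a pre-ranked gene set enrichment score
    with a permutation null and Benjamini-Hochberg FDR, scores embryonic
    stem cell signatures across sample groups, and implements the assay
    statistics used alongside: single-hit limiting-dilution frequency
    estimation with likelihood-ratio group comparison, qPCR 2^-ddCt
    copy-number calling, tumor volume and fold-change metrics, and viability
    normalization. A synthetic-data module generates cell-line panels,
    cohorts, and limiting-dilution plates with the statistical structure
    each stage assumes, so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
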