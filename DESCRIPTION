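Package: mdcmap
Title: Multi-Dataset Gene Signatures and Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease gene signatures by combining signed, normalized
    rank scores of differentially expressed genes across multiple paired
    tumour/normal expression studies, and queries them against a reference
    database of compound-induced expression profiles. Includes per-dataset
    paired differential expression with an adaptive significance threshold,
    cross-dataset score combination, a self-contained signed-rank
    connectivity-mapping engine with Monte-Carlo and exhaustive nulls,
    FDR-guided selection of the signature length, perturbation-stability
    scoring of drug hits, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
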