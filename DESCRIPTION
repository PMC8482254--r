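Package: themetag
Title: Cross-Platform Thematic Label Transfer and Hashtag Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for transferring weak thematic labels across social media
    platforms: posts from themed communities train a binary text classifier
    whose predictions on an unlabeled hashtag-bearing corpus drive a one-sided
    chi-square hashtag enrichment test with Benjamini-Hochberg false discovery
    rate control; the discovered hashtag set defines population-normalized
    geotagged-post prevalence per geographic area, which is associated with
    area-level health outcomes by crude Spearman correlation and
    confounder-adjusted linear regression. A synthetic social-media world with
    planted ground truth (themed communities, enriched hashtags, a linear
    area-level outcome model) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
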