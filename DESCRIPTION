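Package: dmimap
Title: Duplication Mapping of Dominant X-Linked Hybrid Incompatibilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for Dp(1;Y) duplication-mapping
    screens of dominant X-linked hybrid lethality in Drosophila. Provides
    cytological band coordinate parsing and interval arithmetic, a stage-
    structured simulator of attached-X by paternal-species crosses with
    planted dominant lethal loci, stage-specific lethality calling with
    dual-background concordance, minimal lethal-region inference by
    minimum interval piercing, and the statistical layer used to summarise
    such screens (stage-uniformity chi-square tests, Sidak multiple-
    comparison thresholds, and linear-versus-quadratic snowball model
    comparison by Gaussian-likelihood AIC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
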