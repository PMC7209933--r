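Package: fearscore
Title: Multivariate Quantification of Fear Intensity from Physiology, Self-Report and Sweat Volatiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how intensely donors experienced fear during
    sweat-sampling sessions and whether that intensity is encoded in the
    volatiles their sweat emits. Provides a from-scratch two-class partial
    least-squares discriminant analysis (NIPALS) with VIP scores, R2 and
    cross-validated Q2 diagnostics; circumplex clustering of questionnaire
    items by metric multidimensional scaling; MAD-based Winsorization and
    variance-inflation-factor screening; a composite fear score with tertile
    categorization, leave-one-out cross-validation and exact binomial
    above-chance tests; dose-response statistics (paired signed-rank tests,
    linear-contrast ANOVA, Spearman correlation); and quantification plus
    mono/bi-exponential decay modelling of photo-ionization-detector traces
    of sweat headspace. A synthetic-data generator emulates the assumed
    statistical structure of donor datasets and detector traces so the whole
    pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pheatmap
Config/testthat/edition: 3
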