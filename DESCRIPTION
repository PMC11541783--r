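Package: fishrisk
Title: Fish Consumption Risk Assessment for Censored Contaminant Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A One Health pipeline from congener-level, partially left-censored
    contaminant measurements in composite fish samples to human health and
    wildlife risk screening. Provides Kaplan-Meier chemical-class totals for
    nondetect data with half-detection-limit fallback, design-based
    (composite-clustered) means, confidence intervals and two-group t-tests,
    U-score ranking of censored multivariate panels with ANOSIM, Kruskal-Wallis
    and Wilcoxon comparisons and principal-component biplot coordinates,
    WHO 2005 toxic equivalency (TEQ) computation, hazard quotients against
    reference doses, lifetime cancer risk from an oral slope factor,
    fillet-to-whole-fish conversion with wildlife-value screening, and a
    seeded synthetic-data generator calibrated to published concentrations of
    persistent organic chemicals and PFAS in anadromous fish.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    vegan,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
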