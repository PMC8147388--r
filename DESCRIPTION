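Package: lnctox
Title: LncRNA Toxicogenomics: Co-Expression Networks and Exposure Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a long non-coding RNA (lncRNA)
    toxicogenomics workflow for engineered-nanomaterial exposure studies:
    microarray preprocessing (log2 transform, negative-control background
    filtering, quantile normalization, empirical-Bayes batch adjustment),
    per-exposure moderated differential expression with
    Benjamini-Hochberg false-discovery-rate control and fold-change
    gating, lncRNA-mRNA guilt-by-association Pearson correlation networks
    with connectivity filtering and bi-clustering, local hypergeometric
    gene-set over-representation of network modules, and Z-score-based
    ranking of exposures into toxicity tiers. Ships a synthetic-data
    generator with planted ground truth so the entire pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
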