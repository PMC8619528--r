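Package: gutnetdys
Title: Co-Abundance Network Dysbiosis Analysis of Honeybee Gut Microbiota Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-condition genus-level co-abundance networks from 16S
    rRNA transcript-derived activity tables of the honeybee (Apis mellifera)
    gut microbiota, and extracts dysbiosis signatures of sublethal pesticide
    exposure. Implements Spearman correlation screening with dual
    Benjamini-Hochberg and Bonferroni control and an absolute-rho threshold,
    node-level topology metrics (degree, neighborhood connectivity, closeness
    centrality) in the Cytoscape NetworkAnalyzer convention, occurrence and
    low-activity taxon filters, alpha diversity (Chao1, Shannon) with
    Kruskal-Wallis/Dunn comparisons, a median-of-ratios differential activity
    statistic, BLAST-hit lowest-common-ancestor taxonomic assignment,
    Kaplan-Meier survival and per-bee feeding-rate statistics for cage
    experiments, and a seeded synthetic-data generator emulating the full
    caged-bee study design (gut section x dose x cage x replicate) with
    planted rank correlations via a Gaussian copula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    biomformat,
    withr
Config/testthat/edition: 3
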