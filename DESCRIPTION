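Package: screenkit
Title: Anticancer Screening Analytics: Dose-Response Endpoints, Activity
    Fingerprints, Drug-Likeness and Tumor Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analytics for small-molecule anticancer screening
    campaigns in the NCI60 style. Computes percent growth and the GI50/TGI/LC50
    endpoint concentrations with censoring from five-dose plate data, correlates
    per-cell-line activity fingerprints against compound libraries
    (COMPARE-style), aggregates heterogeneous target-prediction outputs into a
    consensus target list, derives graph-based drug-likeness descriptors
    (molecular weight, H-bond donors/acceptors, Ertl topological polar surface
    area, fraction Csp3, rotatable bonds, Lipinski rule-of-five) from MDL
    molfiles, and provides tumor-genomics statistics (alteration frequencies,
    co-occurrence enrichment with Fisher/BH, Kaplan-Meier and log-rank survival)
    plus protein-protein-interaction graph summaries and gene-set enrichment.
    Ships synthetic-data generators with known ground truth for every input
    class so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
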