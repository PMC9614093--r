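Package: csnq
Title: Scoring and Descriptive Analysis of Children's Egocentric Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores child egocentric-network rosters (ego demographics plus a
    per-alter roster of demographics, relationship labels, interaction
    contexts and relationship-intensity measures) into a standard metric set:
    network size, composition (kin, adult and high-intensity proportions with
    a cohort-level z-score median split), structure (context-inferred ties,
    density, connected components, component ratio), and diversity (base-2
    Shannon entropy and E-I homophily indices for race and language,
    component-level entropy and an integrated/segregated/no-diversity
    typology).  Includes a seeded synthetic-cohort generator emulating a
    developmental sample of children aged 6-60 months, cohort-level
    descriptive statistics (Spearman correlations with Benjamini-Hochberg
    adjustment, rank-sum comparisons, age regressions, summary tables), graph
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
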