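Package: pinyonDefense
Title: Drought Constraints on Induced Terpene Defense in Pinyon Pine
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for glasshouse experiments on drought
    limitation of induced mono- and sesquiterpene (MST) defense in
    Pinus edulis inner bark. Provides a girdle resin-loss correction
    for induced MST changes, a stoichiometric ledger for the glucose
    cost of terpene biosynthesis via the MEP or MVA pathway, de novo
    synthesis budgets from nonstructural carbohydrate (NSC) pools,
    inner-bark pressure-potential estimation from vapor-pressure
    osmometry, the associated statistical layer (type-II ANOVA,
    Tukey-HSD, Bray-Curtis PERMANOVA, principal-coordinate
    projection), and a synthetic-cohort generator that emulates the
    experimental design for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    vegan,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
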