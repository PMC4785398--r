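Package: microprov
Title: Microbiota-Based Provenance Analysis of Mosquito Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assigning individual mosquitoes to their
    population of origin from 16S OTU count tables. Implements OTU-table
    handling, depth filtering and rarefaction, Morisita-Horn community
    dissimilarity with NMDS ordination and permutational ANOVA, and a
    repeated double cross-validated (rdCV) random-forest classifier with
    inner-loop backward OTU elimination, together with permutation-based
    null (H0) misclassification populations for model-validity testing.
    Includes a synthetic OTU-table generator emulating village-structured
    whole-body mosquito microbiota so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
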