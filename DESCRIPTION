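Package: fragevo
Title: Evolutionary Dynamics of Vertical Cancer Transmission via Asexual
    Fragmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of cancer evolution in animals that
    reproduce by fissiparity or budding. Models within-organism
    normal/defective/cancerous cell-state dynamics in germline (PGC/APSC) and
    somatic compartments with closed-form solutions, inheritance of parental
    cell composition through detached fragments, analytical classification of
    fragmentational purging versus accumulation regimes via the dominant
    eigenvector of the composed transfer operator, organism-level fitness with
    regeneration and immunity costs, and a discrete-generation pedigree
    recursion over sexually and asexually produced subpopulations with bounded
    population regulation. Ships seven named scenario configurations and
    fitness-surface sweep utilities over fragmentation prevalence and
    cancer-suppression capability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
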