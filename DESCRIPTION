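Package: tnmstager
Title: Exclusionary TNM Cancer Staging Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for assigning anatomic stages under the TNM cancer
    staging system by sequential exclusion rather than combinatorial lookup.
    Given a staging table (stage labels mapped to tumor/node/metastasis
    groupings, including wildcard entries) and a bank of yes/no questions
    derived from classification criteria, the engine polls the surviving
    groupings, ranks classifications by ascending frequency with
    extent-of-spread and level tie-breaks, and prompts selection or exclusion
    of the first-ranked classification until a single stage or grouping
    remains. Includes a JSON codec with validation for authoring staging
    tables, a bundled lung-cancer table, session history with undo/redo, a
    brute-force lookup oracle with a truthful-responder simulator for
    verifying the engine and measuring how many questions staging takes, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
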