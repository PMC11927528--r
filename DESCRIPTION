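Package: postcompose
Title: Post-Composition of Phenotype Trait Ontology Terms and Usage Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds post-composed phenotype trait terms by combining one trait
    ontology term with terms from orthogonal ontologies (object, attribute,
    time, event), mints sequential COMP identifiers, and persists terms in a
    Chado-cvterm-style vocabulary store with "contains" relationships to their
    components. Reads and writes the OBO flat-file subset used to exchange
    trait and orthogonal ontologies. Analyses how post-composed versus
    pre-composed traits are used across breeding accessions: per-accession
    trait counts, elbow-method cluster-number selection, k-means grouping into
    lettered strata with centroid-derived count boundaries, trait-root
    frequencies, and post/pre usage ratios. Ships deterministic generators for
    toy ontologies and synthetic usage tables with planted cluster structure,
    plus a command-line interface over the same functions.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
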