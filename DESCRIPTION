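Package: sramine
Title: Mining and Characterization of Sequence Read Archive Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for indexing Sequence Read Archive (SRA) metadata and
    linking archived sequencing projects to the literature. Parses the six
    SRA metadata object types (submission, study, experiment, run, sample,
    analysis) from their XML files, builds a directed accession graph and
    resolves any accession to its study, recognizes SRA and GEO accessions
    in free text, assembles a deduplicated publication list from metadata
    references, full-text accession extraction and GEO series bridging,
    and characterizes studies by MeSH disease terms with Disease
    Ontology-mediated OMIM links. Includes a deterministic synthetic-corpus
    generator with ground truth so the whole pipeline is testable offline,
    and a command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
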