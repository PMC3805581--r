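# sramine

Mining and characterization of Sequence Read Archive (SRA) metadata in R.

The SRA is the primary public archive of high-throughput sequencing data,
but finding usable entries in it is hard: the metadata is split over six
XML object kinds (submission, study, experiment, run, sample, analysis)
with one-to-many links, much of it is free text, and nothing is quality
controlled. A practical quality criterion is whether a project is cited
by a peer-reviewed article. `sramine` is for bioinformaticians and
curators who want to apply that criterion at desk scale:

* **Accession graph** — parse the six metadata object kinds, build a
  directed graph of their reference links, and resolve any accession
  (run, experiment, sample, analysis, submission) to its study
  accession(s): run → experiment → study, sample through the experiments
  that sequenced it, submission through everything it owns. Results are
  sets, because links are one-to-many.
* **Accession recognition** — regular-expression extraction of SRA
  (`SRP`/`ERX`/`DRR`/… with ≥5 digits) and GEO (`GSE`/`GDS`) accessions
  from free text, with word-boundary rules and offset reporting.
* **Publication list** — (study, PMID) pairs assembled from three
  provenance routes: PubMed references inside the metadata, SRA
  accessions extracted from article full text, and GEO series bridging
  (for data whose raw reads live in GEO while SRA holds the metadata).
  Citations that resolve to no project are dropped and logged — the
  false-positive omission filter. Merged lists are deduplicated on the
  (study, PMID) key with deterministic provenance priority, and evaluated
  against a gold standard as precision = tp/(tp+fp), recall = tp/(tp+fn).
* **Disease index** — studies annotated with the MeSH headings of their
  linked articles, restricted to the Diseases branch (`C…`) and Mental
  Disorders sub-branch (`F03`); frequency list over distinct studies; a
  hierarchy view with distinct-study roll-ups; and MeSH → OMIM mapping
  through Disease Ontology xrefs, used to hyperlink Gendoo disease
  feature profiles.
* **Synthetic corpus** — a deterministic generator writes a complete
  miniature snapshot (SRA XML, MEDLINE + full texts, GEO SOFT, MeSH and
  Disease Ontology slices) with ground truth, so the whole pipeline is
  testable offline.

See the vignette in `vignettes/sra-metadata-mining.Rmd` for the methods
in detail.

## Worked example

```r
library(sramine)

corpus <- generate_corpus(corpus_config(n_studies = 6, n_articles = 8,
                                        geo_fraction = 0.3, seed = 42),
                          "demo_corpus")
res <- run_pipeline("demo_corpus", "demo_out")

res$index$graph
#> <accession_graph> 42 objects, 66 links (1 dangling)
#>   submission: 6, study: 5, experiment: 9, run: 12, sample: 10, analysis: 0
```

Forty-two metadata objects were parsed into the graph; one reference link
dangles (a submission deposited experiments whose study object is
missing — data, not an error). Five of the six intended studies are
therefore resolvable projects:

```r
res$index$projects[, c("study_accession", "study_type", "n_experiments", "n_runs")]
#> # A tibble: 5 × 4
#>   study_accession study_type              n_experiments n_runs
#> 1 SRP000004       Metagenomics                        3      4
#> 2 SRP000003       Whole Genome Sequencing             2      3
#> 3 SRP000005       Epigenetics                         2      2
#> ...
```

The merged publication list carries each pair's provenance — note the
GEO-hosted study SRP000003, whose articles cite the series GSE101 and
which is reachable only across the bridge:

```r
tibble::as_tibble(res$lit$links)
#> # A tibble: 8 × 4
#>   study_accession     pmid provenance      raw_accession
#> 1 SRP000002       20000001 fulltext_direct SRX000002
#> 2 SRP000002       20000006 fulltext_direct SRP000002
#> 3 SRP000003       20000002 geo_bridge      GSE101
#> 4 SRP000003       20000007 geo_bridge      GSE101
#> ...

evaluate_pairs(res$lit$links, corpus$ground_truth$true_pairs)
#> # A tibble: 1 × 5
#>      tp    fp    fn precision recall
#> 1     8     0     0         1      1
```

All eight planted (study, PMID) pairs were recovered with no false
positives. The disease frequency list counts distinct studies per MeSH
disease term, with OMIM ids attached where the Disease Ontology links
them:

```r
res$disease$frequency
#> # A tibble: 6 × 4
#>   name                ui      n_projects omim_ids
#> 1 Alzheimer Disease   D000544          3 <int [1]>
#> 2 Prostatic Neoplasms D011471          3 <int [1]>
#> 3 Breast Neoplasms    D001943          2 <int [1]>
#> ...
```

`demo_out/` now holds the published reports: `project_list.tsv`,
`completeness.tsv`, `publication_list.tsv`, `drop_log.tsv`,
`disease_associations.tsv`, `disease_frequency.tsv`,
`disease_tree.json` and the three `stats_by_*.tsv` facet tables.

A command-line interface over the same stages ships in
`inst/cli/sramine` (subcommands `index`, `litlink`, `disease`, `stats`,
`fixtures`, `evaluate`, `run`).

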