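---
title: "Mining SRA metadata: accession graphs, publication links and disease indexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SRA metadata: accession graphs, publication links and disease indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sramine)
```

## The problem

The Sequence Read Archive (SRA) is the primary public archive of
high-throughput sequencing data, synchronized between NCBI, EBI and DDBJ.
Its experimental metadata is split over six XML object kinds — submission,
study, experiment, run, sample and analysis — connected by one-to-many
reference links, and most submissions deposit only a subset of the six.
Because anyone can submit without quality control, a practical proxy for
data quality is whether an archived project is cited by a peer-reviewed
article. `sramine` implements the desk-scale machinery for that idea:

1. parse the six metadata object kinds and build a directed **accession
   graph**, so any accession can be resolved to its study ("project");
2. assemble a **publication list** of (study, PMID) pairs from three
   provenance routes — PubMed references inside the metadata, SRA
   accessions extracted from article full text, and GEO series bridging;
3. build a **disease index** of studies from the MeSH headings of the
   linked articles, restricted to the disease branches, with Disease
   Ontology–mediated OMIM links out to the Gendoo disease profiles.

A deterministic synthetic-corpus generator with ground truth makes every
stage testable offline; no archive download is involved anywhere.

## The accession graph and resolution semantics

Every reference link in the metadata becomes a directed, typed edge.
Resolution to the study level follows the natural topology:
run → experiment → study, analysis → study, and sample → experiment →
study via the experiments that sequenced the sample (the reverse of the
experiment → sample link); a submission resolves through everything it
owns; a study resolves to itself. Because links are one-to-many, the
result is always a *set* of study accessions — downstream consumers fan
out pairs over the set rather than picking one.

Two deliberately distinct failure modes exist. A syntactically invalid
token is a programming error and raises; a well-formed accession unknown
to the graph returns the empty set. The empty set is load-bearing: a
citation whose accession resolves to nothing has no corresponding project
information, and the publication-list stage drops it (and logs the
mention) rather than emitting an unverifiable pair. That omission filter
is what keeps precision at 1.0 when syntactically plausible decoy
accessions appear in article text.

Links pointing at absent objects are kept as *dangling* edges, not
errors: incomplete submissions are a normal feature of the archive, which
is also why completeness profiles (which object kinds each submission
deposited) are a first-class report.

Reachability itself is ordinary BFS, delegated to `igraph` over a
precomputed "resolution graph" whose edges are exactly the legal steps
above. The test suite checks it against an independent brute-force
fixed-point oracle written without igraph.

### The XML dialect

The archive schema does not express submission ownership inside the
record elements, so the dialect read here allows a `SUBMISSION` record to
carry `STUDY_REF`/`EXPERIMENT_REF`/`RUN_REF`/`SAMPLE_REF`/`ANALYSIS_REF`
children, in the same style as the `*_REF` elements the schema already
uses elsewhere. `XREF_LINK` entries are accepted with `DB`/`ID` as
attributes or as child elements; `DB="pubmed"` entries become PubMed
cross-references. Everything outside the dialect is ignored silently, so
richer real dumps still parse. Duplicate accessions merge last-wins with
a warning — the deterministic choice for incremental dumps. Accessions
are canonicalized to uppercase with dot-version suffixes stripped.

## Recognizing accessions in text

Accession extraction is regular-expression matching with word boundaries:
a match may not be preceded or followed by a letter or digit, so hyphens,
dots and parentheses delimit (and `"SRP001234."` matches without the
dot), while `"SRAdb"` or `"xSRP001234"` do not match at all. SRA
accessions require at least five digits after the three-letter prefix
(real accessions carry six or more; five tolerates compact fixtures), GEO
accessions at least one digit after `GSE`/`GDS`. Matching is
uppercase-only by default — the conservative choice against prose false
positives — with an opt-in case-insensitive flag. Offsets are reported
0-based with an exclusive end, the common text-mining convention.
Analysis-level prefixes (`SRZ`/`ERZ`/`DRZ`) are recognized for
completeness even though they are rarely cited.

## The publication list

The three routes produce links tagged with their provenance:

* `metadata_ref` — every PubMed cross-reference carried by any metadata
  object, with the carrying object resolved to its study;
* `fulltext_direct` — SRA accessions extracted from article full text,
  resolved likewise, with the drop log recording every unresolvable
  mention. The restriction to articles carrying the "High-Throughput
  Nucleotide Sequencing" MeSH heading applies to this route only and is
  controllable by a flag;
* `geo_bridge` — since 2011 much transcriptome raw data lives in GEO
  while SRA holds only metadata, so articles often cite a GEO series.
  The bridge is assembled from both directions (SRA accessions named in
  GEO records; GEO accessions mentioned in SRA titles/links) and PMIDs
  attached to GEO records — their own `pubmed_id` fields plus articles
  citing the series — are carried across to the study.

Manually curated pairs can be ingested from a side table; they bypass
extraction but still must resolve. Merging deduplicates on the
(study, PMID) key; when several routes find the same pair, the kept
provenance follows a fixed priority (`metadata_ref` > `fulltext_direct` >
`geo_bridge` > `manual`). The priority is an arbitrary but deterministic
convention: it makes merged output independent of argument order, which
the suite asserts.

Evaluation is plain set arithmetic against a gold standard: precision
tp/(tp+fp), recall tp/(tp+fn), with undefined ratios reported as `NA`
rather than 0 so an empty prediction set is not mistaken for a totally
wrong one.

## The disease index

Studies are annotated with the MeSH headings of their linked articles,
restricted to descriptors with any tree number in the Diseases branch
(`C…`) or the Mental Disorders sub-branch (`F03` at a code boundary, so
hypothetical `F030…` codes cannot leak in). Any-match semantics are used:
a descriptor with one disease position among several qualifies. Headings
are matched by exact preferred name or UI only; lexical variants ("breast
cancer" vs. "Breast Neoplasms") are deliberately not resolved — the
hierarchy view, not synonym matching, is the answer to term multiplicity.

The frequency list counts **distinct studies** per descriptor (not pairs
or submissions). The tree view materializes each annotated descriptor at
every one of its tree positions plus all ancestors; `own_count` is the
number of distinct studies annotated exactly at a node, `rolled_count`
the distinct studies anywhere in its subtree, so a study annotated at two
siblings still counts once at their parent.

MeSH→OMIM mapping goes through Disease Ontology xrefs: every non-obsolete
term carrying both an `MSH` and one or more `OMIM` xrefs contributes its
OMIM ids (union over terms). Descriptors never co-mentioned with OMIM map
to the empty set — a real phenomenon (the ontology simply has no link for
some diseases, lung neoplasms being the canonical example), which is why
the association report leaves the Gendoo column blank rather than
guessing. Obsolete terms are excluded. The mapping is monotone: adding
terms never removes an association.

## The synthetic corpus

`generate_corpus()` writes a fully self-consistent miniature snapshot:
six SRA XML files, MEDLINE records with plain-text full texts, a GEO SOFT
series file, a MeSH vocabulary slice and a Disease Ontology slice, plus
TSV ground truth for every planted fact. The same configuration and seed
reproduce the corpus byte for byte (the generator saves and restores the
RNG state around its work).

Default conditions, chosen once to mirror the character of the archive:

* 20 studies, one submission each; 1–3 experiments per study, 1–2 runs
  per experiment; completeness mix dominated by the
  submission+study+experiment+run+sample pattern (0.55), with analysis
  present in 0.20 of submissions and tails of incomplete patterns
  including a missing-study pattern that exercises dangling links;
* 30 articles; cited accession level mixed over study (0.5), experiment
  (0.3) and run (0.2), since articles frequently cite below study level;
* a 0.3 chance that an article's PMID is also referenced in the study
  metadata and a 0.9 chance that its full text cites the accession (the
  metadata route is forced when neither fires, so every planted pair
  remains recoverable by construction);
* taxa and platforms drawn from small embedded pools (human, mouse, fruit
  fly, marine metagenome, yeast; common Illumina/454/SOLiD instruments)
  so the facet tables look like real archive statistics;
* `decoy_rate` and `geo_fraction` both 0 by default; tests and the
  acceptance checks switch them on explicitly (decoys at 2 mentions per
  article, GEO hosting at 0.3) to probe the omission filter and the
  bridge ablation.

Decoys are *syntactically valid* accessions absent from the metadata —
the filter under test operates at resolution time, not regex time, so
malformed strings would probe the wrong thing. GEO-hosted studies are
reachable only across the bridge by construction: disabling the GEO route
must lose exactly those pairs, a prediction the ground truth makes
checkable.

What the generator does not emulate: real prose (full texts are
templated sentences), PDFs and supplementary files, journal-site HTML,
OCR noise, heading assignment errors, or the scale of the real corpora.
Passing tests therefore demonstrate the correctness of the mechanisms —
resolution, filtering, merging, counting — not the precision/recall the
same patterns would achieve on real full text.

## Problem sizes and runtime choices

The suite runs the resolution oracle on 100 random graphs (a few dozen
objects each), the evaluator oracle on 1000 random set pairs, end-to-end
recovery on 20-study/30-article corpora and determinism on a 15-study
double run; together they complete in about two minutes on one core.
These sizes were picked as the smallest at which every mechanism
(one-to-many fan-out, shared samples, dangling links, all three routes,
both bridge directions) is exercised repeatedly per run.

## Known limitations

* Heading matching is exact; entry terms/synonyms are out of scope.
* Study-type, platform and species facets reflect whatever the metadata
  declares; no normalization of instrument names or taxa is attempted.
* A study spanning several submissions is keyed by its study accession;
  submission-level bookkeeping appears only in the completeness report.
* The drop log records unresolvable mentions but no attempt is made to
  classify *why* a mention failed (typo, withdrawn record, out-of-dialect
  archive).
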