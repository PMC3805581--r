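# Pipeline stages behind the command-line interface: each run_* function
# reads the declared inputs, executes one stage, writes its reports with
# stable ordering (same inputs -> byte-identical outputs) and returns the
# result invisibly for programmatic use.

.require_path <- function(path, what) {
  if (!file.exists(path)) abort(paste0("missing ", what, ": ", path))
  path
}

#' Standard layout of a corpus directory
#'
#' @param dir Corpus root (as written by [generate_corpus()]).
#' @return Named list of input paths: `sra`, `medline`, `fulltext`, `soft`,
#'   `mesh`, `obo`.
#' @export
corpus_paths <- function(dir) {
  list(
    sra = file.path(dir, "sra"),
    medline = file.path(dir, "articles", "medline.txt"),
    fulltext = file.path(dir, "articles", "fulltext"),
    soft = file.path(dir, "geo", "series.soft"),
    mesh = file.path(dir, "vocab", "mesh.bin"),
    obo = file.path(dir, "vocab", "do.obo")
  )
}

.collapse_col <- function(x) map_chr(x, paste, collapse = ",")

#' Write the project list TSV
#'
#' @param projects Output of [summarize_projects()].
#' @param path Output file.
#' @return The flattened tibble that was written, invisibly.
#' @export
write_project_list <- function(projects, path) {
  flat <- projects |>
    mutate(
      platforms = .collapse_col(.data$platforms),
      taxa = map_chr(.data$taxa, function(t)
        paste(t$scientific_name, collapse = ",")),
      submissions = .collapse_col(.data$submissions)
    )
  readr::write_tsv(flat, path, na = "")
  invisible(flat)
}

#' Index stage: parse SRA metadata, build the graph, write project reports
#'
#' Writes `project_list.tsv` (one study per row, platforms and taxa
#' comma-joined) and `completeness.tsv` (submission presence/absence
#' patterns with counts).
#'
#' @param sra_dir Directory with the six `*.xml` metadata files.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `graph`, `projects`, `profiles`.
#' @export
run_index <- function(sra_dir, out_dir) {
  .require_path(sra_dir, "SRA metadata directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  objects <- read_sra_dir(sra_dir)
  graph <- build_accession_graph(objects)
  projects <- summarize_projects(graph)
  profiles <- completeness_profiles(graph)
  write_project_list(projects, file.path(out_dir, "project_list.tsv"))
  readr::write_tsv(profiles, file.path(out_dir, "completeness.tsv"), na = "")
  invisible(list(graph = graph, projects = projects, profiles = profiles))
}

#' Literature stage: assemble the publication list over all routes
#'
#' Gathers (study, PMID) pairs from the metadata references, from SRA
#' accessions extracted out of article full text, and across the GEO
#' bridge; merges and deduplicates them; writes `publication_list.tsv`
#' (with study titles) and `drop_log.tsv` (every citation mention dropped
#' because it resolves to no project).
#'
#' @param sra_dir Directory with the SRA metadata XML files.
#' @param medline Path to the MEDLINE file (optional: `NULL` skips the
#'   article-based routes).
#' @param fulltext_dir Directory of `<pmid>.txt` full texts (optional).
#' @param soft Path to the GEO SOFT file (optional: `NULL` disables the
#'   GEO bridge).
#' @param out_dir Output directory.
#' @param hts_only Restrict the full-text route to articles carrying the
#'   high-throughput sequencing heading.
#' @param use_geo Run the GEO bridge route at all; `FALSE` ablates it (no
#'   bridge is built, GEO citations contribute nothing).
#' @param manual Optional data frame (or TSV path) of hand-curated
#'   `accession`, `pmid` pairs.
#' @param case_insensitive Match accessions case-insensitively in text.
#' @return Invisibly, a list with `links` (merged publication list, drop
#'   log attached), `graph`, `articles`, `geo_records`, `bridge`.
#' @export
run_litlink <- function(sra_dir, medline = NULL, fulltext_dir = NULL,
                        soft = NULL, out_dir, hts_only = TRUE,
                        use_geo = TRUE, manual = NULL,
                        case_insensitive = FALSE) {
  .require_path(sra_dir, "SRA metadata directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  objects <- read_sra_dir(sra_dir)
  graph <- build_accession_graph(objects)

  articles <- tibble(pmid = integer(), title = character(),
                     mesh_headings = list(), is_hts = logical(),
                     full_text = character())
  if (!is.null(medline)) {
    .require_path(medline, "MEDLINE file")
    if (!is.null(fulltext_dir)) .require_path(fulltext_dir, "full-text directory")
    articles <- read_article_corpus(medline, fulltext_dir)
  }
  geo_records <- tibble(accession = character(), kind = character(),
                        pubmed_ids = list(), sra_relations = list())
  if (use_geo && !is.null(soft)) {
    .require_path(soft, "GEO SOFT file")
    geo_records <- read_geo_soft(soft)
  }
  if (is.character(manual) && length(manual) == 1) {
    manual <- readr::read_tsv(.require_path(manual, "manual pair file"),
                              show_col_types = FALSE)
  }

  meta_links <- pmids_from_metadata(objects, graph)
  text_links <- pairs_from_fulltext(articles, graph, hts_only = hts_only)
  if (use_geo) {
    bridge <- build_geo_bridge(geo_records, objects, graph)
    geo_links <- pairs_via_geo(geo_records, articles, bridge)
  } else {
    bridge <- tibble(geo_accession = character(),
                     study_accession = character(), source = character())
    geo_links <- .empty_links()
  }
  man_links <- manual_pairs(manual, graph)
  links <- merge_publication_list(meta_links, text_links, geo_links, man_links)

  titles <- graph$nodes |>
    filter(.data$kind == "study") |>
    select(study_accession = "accession", study_title = "title")
  out <- as_tibble(links) |>
    left_join(titles, by = "study_accession") |>
    select("study_accession", "study_title", "pmid", "provenance",
           "raw_accession")
  readr::write_tsv(out, file.path(out_dir, "publication_list.tsv"), na = "")
  readr::write_tsv(drop_log(links), file.path(out_dir, "drop_log.tsv"), na = "")
  invisible(list(links = links, graph = graph, articles = articles,
                 geo_records = geo_records, bridge = bridge))
}

#' Disease stage: annotate studies with MeSH disease terms
#'
#' Crosses the publication list with article MeSH headings restricted to
#' the Diseases branch / Mental Disorders sub-branch, maps the descriptors
#' to OMIM through the Disease Ontology, and writes three reports: the
#' association list `disease_associations.tsv` (with Gendoo links where an
#' OMIM mapping exists), the frequency list `disease_frequency.tsv`, and
#' the hierarchy `disease_tree.json`.
#'
#' @param links Publication link tibble (e.g. from [run_litlink()]).
#' @param articles Article tibble with MeSH headings.
#' @param mesh Path to (or text of) the MeSH ASCII descriptor file.
#' @param obo Path to (or text of) the Disease Ontology OBO file.
#' @param out_dir Output directory.
#' @param graph Optional `accession_graph` used to attach study titles.
#' @param gendoo_template URL template passed to [gendoo_url()].
#' @return Invisibly, a list with `annotations`, `frequency`, `tree`,
#'   `mesh_omim`.
#' @export
run_disease <- function(links, articles, mesh, obo, out_dir, graph = NULL,
                        gendoo_template = formals(gendoo_url)$template) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vocab <- parse_mesh_ascii(mesh)
  do_terms <- parse_do_obo(obo)
  mapping <- mesh_to_omim(do_terms)
  annotations <- annotate_diseases(links, articles, vocab)
  freq <- disease_frequency(annotations, mesh_omim = mapping)
  tree <- build_disease_tree(annotations, vocab)

  titles <- tibble(study_accession = character(), study_title = character())
  if (!is.null(graph)) {
    titles <- graph$nodes |>
      filter(.data$kind == "study") |>
      select(study_accession = "accession", study_title = "title")
  }
  omim_of <- stats::setNames(freq$omim_ids, freq$ui)
  assoc <- annotations |>
    left_join(titles, by = "study_accession") |>
    mutate(
      study_title = if ("study_title" %in% names(titles) && nrow(titles) > 0)
        .data$study_title else NA_character_,
      supporting_pmids = .collapse_col(.data$supporting_pmids),
      gendoo_url = map_chr(.data$ui, function(u) {
        ids <- omim_of[[u]]
        if (is.null(ids) || length(ids) == 0) ""
        else paste(gendoo_url(ids, template = gendoo_template), collapse = ",")
      })
    ) |>
    select("study_accession", "study_title", "ui", disease_name = "name",
           "supporting_pmids", "gendoo_url")
  readr::write_tsv(assoc, file.path(out_dir, "disease_associations.tsv"), na = "")
  readr::write_tsv(
    freq |> mutate(omim_ids = .collapse_col(.data$omim_ids)),
    file.path(out_dir, "disease_frequency.tsv"), na = "")
  jsonlite::write_json(tree_as_list(tree),
                       file.path(out_dir, "disease_tree.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       na = "null")
  invisible(list(annotations = annotations, frequency = freq, tree = tree,
                 mesh_omim = mapping))
}

#' Stats stage: facet summaries of the project list
#'
#' Writes `stats_by_study_type.tsv`, `stats_by_platform.tsv` and
#' `stats_by_taxon.tsv` — study counts per category, where a study counts
#' once under each category it carries.
#'
#' @param projects Output of [summarize_projects()].
#' @param out_dir Output directory.
#' @return Invisibly, the named list of facet tibbles.
#' @export
run_stats <- function(projects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  facets <- c("study_type", "platform", "taxon")
  out <- stats::setNames(map(facets, function(f) {
    tab <- tabulate_by(projects, f)
    readr::write_tsv(tab, file.path(out_dir, paste0("stats_by_", f, ".tsv")),
                     na = "")
    tab
  }), facets)
  invisible(out)
}

#' Run the whole pipeline over a corpus directory
#'
#' Convenience wrapper chaining [run_index()], [run_litlink()],
#' [run_disease()] and [run_stats()] over the standard corpus layout.
#'
#' @param corpus_dir Corpus root (see [corpus_paths()]).
#' @param out_dir Output directory.
#' @param hts_only,use_geo,manual Stage options; `use_geo = FALSE` disables
#'   the GEO bridge route entirely (ablation).
#' @return Invisibly, a list with the stage results (`index`, `lit`,
#'   `disease`, `stats`).
#' @export
run_pipeline <- function(corpus_dir, out_dir, hts_only = TRUE,
                         use_geo = TRUE, manual = NULL) {
  p <- corpus_paths(corpus_dir)
  idx <- run_index(p$sra, out_dir)
  lit <- run_litlink(
    p$sra,
    medline = if (file.exists(p$medline)) p$medline else NULL,
    fulltext_dir = if (dir.exists(p$fulltext)) p$fulltext else NULL,
    soft = if (file.exists(p$soft)) p$soft else NULL,
    out_dir = out_dir, hts_only = hts_only, use_geo = use_geo,
    manual = manual
  )
  dis <- run_disease(lit$links, lit$articles, p$mesh, p$obo, out_dir,
                     graph = idx$graph)
  st <- run_stats(idx$projects, out_dir)
  invisible(list(index = idx, lit = lit, disease = dis, stats = st))
}

#' Load a pipeline run configuration from YAML
#'
#' Recognized keys: `corpus_dir`, `out_dir`, `sra_dir`, `medline`,
#' `fulltext_dir`, `soft`, `mesh`, `obo`, `hts_only`, `use_geo`, `manual`,
#' `case_insensitive_accessions`, `gendoo_template`, `seed`. Unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
load_run_config <- function(path) {
  .require_path(path, "configuration file")
  cfg <- yaml::read_yaml(path)
  allowed <- c("corpus_dir", "out_dir", "sra_dir", "medline", "fulltext_dir",
               "soft", "mesh", "obo", "hts_only", "use_geo", "manual",
               "case_insensitive_accessions", "gendoo_template", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  cfg
}
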