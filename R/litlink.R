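# Building the publication list: (study, PMID) pairs gathered over three
# provenance routes -- PubMed references inside the SRA metadata, SRA
# accessions extracted from article full text, and GEO series bridging --
# then merged and deduplicated. Accessions that cannot be resolved to a
# study are dropped (the false-positive omission filter: a citation with no
# corresponding project information is discarded) and logged.

.empty_links <- function() {
  tibble(study_accession = character(), pmid = integer(),
         provenance = character(), raw_accession = character())
}

.empty_drop_log <- function() {
  tibble(pmid = integer(), accession = character(), route = character())
}

.with_drop_log <- function(links, log) {
  attr(links, "drop_log") <- log
  links
}

#' Dropped-accession log of a link table
#'
#' Routes that resolve cited accessions record every mention they had to
#' discard because no corresponding project exists in the graph.
#'
#' @param links A link tibble returned by one of the pairing routes.
#' @return Tibble `pmid`, `accession`, `route` (one row per dropped
#'   mention).
#' @export
drop_log <- function(links) {
  log <- attr(links, "drop_log", exact = TRUE)
  if (is.null(log)) .empty_drop_log() else log
}

#' Publication links cited inside the SRA metadata
#'
#' Every PubMed cross-reference carried by any metadata object becomes a
#' (study, PMID) link, with the carrying object resolved to its study
#' accession(s). Objects whose study cannot be resolved are not emitted;
#' their citations go to the drop log.
#'
#' @param objects Metadata object tibble.
#' @param graph The `accession_graph` over (at least) those objects.
#' @return Link tibble (`study_accession`, `pmid`, `provenance =
#'   "metadata_ref"`, `raw_accession`) with a [drop_log()] attribute.
#' @export
pmids_from_metadata <- function(objects, graph) {
  carriers <- objects |>
    filter(lengths(.data$pubmed_refs) > 0) |>
    select("accession", "pubmed_refs") |>
    tidyr::unnest_longer("pubmed_refs", values_to = "pmid")
  if (nrow(carriers) == 0) return(.with_drop_log(.empty_links(), .empty_drop_log()))
  resolved <- resolve_studies(graph, carriers$accession)
  links <- carriers |>
    dplyr::inner_join(resolved, by = "accession",
                      relationship = "many-to-many") |>
    dplyr::transmute(
      study_accession = .data$study_accession,
      pmid = as.integer(.data$pmid),
      provenance = "metadata_ref",
      raw_accession = .data$accession
    ) |>
    distinct() |>
    arrange(.data$study_accession, .data$pmid)
  dropped <- carriers |>
    filter(!.data$accession %in% resolved$accession) |>
    dplyr::transmute(pmid = as.integer(.data$pmid),
                     accession = .data$accession, route = "metadata_ref")
  .with_drop_log(links, dropped)
}

#' Publication links from accessions cited in article full text
#'
#' Extracts SRA accessions from each article's full text, resolves each to
#' its study, and fans out one link per (study, PMID). Mentions that
#' resolve to no study — syntactically valid accessions absent from the
#' archive snapshot — are dropped and logged, mention by mention; this is
#' the omission filter that keeps false-positive matches out of the
#' publication list.
#'
#' @param articles Article tibble (see [read_article_corpus()]): `pmid`,
#'   `full_text`, `is_hts`.
#' @param graph An `accession_graph`.
#' @param hts_only Restrict to articles carrying the high-throughput
#'   sequencing MeSH heading (default), mirroring how full-text mining is
#'   focused on sequencing articles.
#' @return Link tibble with `provenance = "fulltext_direct"` and a
#'   [drop_log()] attribute.
#' @export
pairs_from_fulltext <- function(articles, graph, hts_only = TRUE) {
  arts <- articles
  if (hts_only) arts <- arts |> filter(.data$is_hts)
  arts <- arts |> filter(!is.na(.data$full_text))
  if (nrow(arts) == 0) return(.with_drop_log(.empty_links(), .empty_drop_log()))
  mentions <- extract_accessions(arts$full_text) |>
    filter(.data$archive != "GEO") |>
    mutate(pmid = arts$pmid[.data$source],
           accession = normalize_accession(.data$accession))
  if (nrow(mentions) == 0) return(.with_drop_log(.empty_links(), .empty_drop_log()))
  resolved <- resolve_studies(graph, mentions$accession)
  links <- mentions |>
    dplyr::inner_join(resolved, by = "accession",
                      relationship = "many-to-many") |>
    dplyr::transmute(
      study_accession = .data$study_accession,
      pmid = as.integer(.data$pmid),
      provenance = "fulltext_direct",
      raw_accession = .data$accession
    ) |>
    distinct() |>
    arrange(.data$study_accession, .data$pmid)
  dropped <- mentions |>
    filter(!.data$accession %in% resolved$accession) |>
    dplyr::transmute(pmid = as.integer(.data$pmid),
                     accession = .data$accession, route = "fulltext_direct")
  .with_drop_log(links, dropped)
}

#' Pair GEO records with SRA studies
#'
#' Since 2011 much transcriptome raw data lives in GEO while SRA holds only
#' the metadata, so articles often cite a GEO series where the sequencing
#' project is an SRA study. The bridge is built from both directions:
#' (i) SRA accessions named in GEO records (`sra_relations`), resolved to
#' studies; (ii) GEO accessions mentioned in SRA object titles or
#' cross-reference links, attached to the studies those objects resolve to.
#' Pairs found both ways are kept once, with `from_geo_record` preferred.
#'
#' @param geo_records GEO tibble from [read_geo_soft()].
#' @param objects Metadata object tibble.
#' @param graph An `accession_graph`.
#' @return Tibble `geo_accession`, `study_accession`, `source`.
#' @export
build_geo_bridge <- function(geo_records, objects, graph) {
  empty <- tibble(geo_accession = character(), study_accession = character(),
                  source = character())
  from_geo <- empty
  if (nrow(geo_records) > 0) {
    rel <- geo_records |>
      select(geo_accession = "accession", "sra_relations") |>
      tidyr::unnest_longer("sra_relations", values_to = "accession")
    if (nrow(rel) > 0) {
      resolved <- resolve_studies(graph, normalize_accession(rel$accession))
      from_geo <- rel |>
        mutate(accession = normalize_accession(.data$accession)) |>
        dplyr::inner_join(resolved, by = "accession",
                          relationship = "many-to-many") |>
        dplyr::transmute(geo_accession = .data$geo_accession,
                         study_accession = .data$study_accession,
                         source = "from_geo_record") |>
        distinct()
    }
  }
  from_sra <- empty
  if (nrow(objects) > 0) {
    scan_text <- paste(
      dplyr::coalesce(objects$title, ""),
      map_chr(objects$xrefs, function(x) paste(x$id, collapse = " "))
    )
    geo_hits <- extract_accessions(scan_text) |>
      filter(.data$archive == "GEO") |>
      mutate(carrier = objects$accession[.data$source])
    if (nrow(geo_hits) > 0) {
      resolved <- resolve_studies(graph, geo_hits$carrier)
      from_sra <- geo_hits |>
        dplyr::inner_join(resolved, by = c(carrier = "accession"),
                          relationship = "many-to-many") |>
        dplyr::transmute(geo_accession = .data$accession,
                         study_accession = .data$study_accession,
                         source = "from_sra_metadata") |>
        distinct()
    }
  }
  bind_rows(from_geo, from_sra) |>
    mutate(.pref = match(.data$source, c("from_geo_record", "from_sra_metadata"))) |>
    arrange(.data$geo_accession, .data$study_accession, .data$.pref) |>
    distinct(.data$geo_accession, .data$study_accession, .keep_all = TRUE) |>
    select(-".pref")
}

#' Publication links carried across the GEO bridge
#'
#' PMIDs attached to a GEO record — from its own `pubmed_id` fields, plus
#' articles whose full text cites the GEO accession — are transferred to
#' the bridged SRA study.
#'
#' @param geo_records GEO tibble from [read_geo_soft()].
#' @param articles Article tibble (may be empty; then only the records'
#'   own PMIDs are used).
#' @param bridge Output of [build_geo_bridge()].
#' @return Link tibble with `provenance = "geo_bridge"` and
#'   `raw_accession` set to the GEO accession.
#' @export
pairs_via_geo <- function(geo_records, articles, bridge) {
  if (nrow(bridge) == 0) return(.empty_links())
  own <- geo_records |>
    select(geo_accession = "accession", "pubmed_ids") |>
    tidyr::unnest_longer("pubmed_ids", values_to = "pmid")
  cited <- tibble(geo_accession = character(), pmid = integer())
  arts <- articles |> filter(!is.na(.data$full_text))
  if (nrow(arts) > 0) {
    hits <- extract_accessions(arts$full_text) |>
      filter(.data$archive == "GEO")
    if (nrow(hits) > 0) {
      cited <- tibble(geo_accession = hits$accession,
                      pmid = arts$pmid[hits$source])
    }
  }
  geo_pmids <- bind_rows(own, cited) |>
    filter(!is.na(.data$pmid)) |>
    distinct()
  geo_pmids |>
    dplyr::inner_join(bridge, by = "geo_accession",
                      relationship = "many-to-many") |>
    dplyr::transmute(
      study_accession = .data$study_accession,
      pmid = as.integer(.data$pmid),
      provenance = "geo_bridge",
      raw_accession = .data$geo_accession
    ) |>
    distinct() |>
    arrange(.data$study_accession, .data$pmid)
}

#' Manually curated publication pairs
#'
#' Ingests a side table of hand-collected (accession, PMID) pairs — e.g.
#' identifiers found in supplementary PDFs — and resolves them like any
#' other citation; pairs that do not resolve go to the drop log.
#'
#' @param pairs Data frame with columns `accession` and `pmid`.
#' @param graph An `accession_graph`.
#' @return Link tibble with `provenance = "manual"` and a [drop_log()]
#'   attribute.
#' @export
manual_pairs <- function(pairs, graph) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(.with_drop_log(.empty_links(), .empty_drop_log()))
  pairs <- as_tibble(pairs) |>
    mutate(accession = normalize_accession(.data$accession))
  resolved <- resolve_studies(graph, pairs$accession)
  links <- pairs |>
    dplyr::inner_join(resolved, by = "accession",
                      relationship = "many-to-many") |>
    dplyr::transmute(study_accession = .data$study_accession,
                     pmid = as.integer(.data$pmid),
                     provenance = "manual",
                     raw_accession = .data$accession) |>
    distinct() |>
    arrange(.data$study_accession, .data$pmid)
  dropped <- pairs |>
    filter(!.data$accession %in% resolved$accession) |>
    dplyr::transmute(pmid = as.integer(.data$pmid),
                     accession = .data$accession, route = "manual")
  .with_drop_log(links, dropped)
}

.provenance_priority <- c("metadata_ref", "fulltext_direct", "geo_bridge", "manual")

#' Merge link tables into the deduplicated publication list
#'
#' Union of all routes, deduplicated on the (study, PMID) key. When the
#' same pair was found by several routes the highest-priority provenance is
#' kept (`metadata_ref` > `fulltext_direct` > `geo_bridge` > `manual`), so
#' output is deterministic regardless of argument order.
#'
#' @param ... Link tibbles.
#' @return Link tibble sorted by study accession then PMID; drop logs of
#'   the inputs are concatenated onto the result's [drop_log()].
#' @export
merge_publication_list <- function(...) {
  inputs <- list(...)
  logs <- bind_rows(map(inputs, drop_log))
  all <- bind_rows(map(inputs, function(x) as_tibble(x)))
  if (nrow(all) == 0) return(.with_drop_log(.empty_links(), logs))
  merged <- all |>
    mutate(.pref = match(.data$provenance, .provenance_priority)) |>
    arrange(.data$study_accession, .data$pmid, .data$.pref, .data$raw_accession) |>
    distinct(.data$study_accession, .data$pmid, .keep_all = TRUE) |>
    select(-".pref")
  .with_drop_log(merged, logs)
}

#' Precision and recall of a predicted pair set
#'
#' Set-based evaluation of predicted (study, PMID) pairs against a gold
#' standard: `tp = |predicted ∩ gold|`, `fp = |predicted \ gold|`,
#' `fn = |gold \ predicted|`; `precision = tp/(tp+fp)` and
#' `recall = tp/(tp+fn)`. An undefined ratio (empty denominator) is
#' reported as `NA`, deliberately distinct from 0.
#'
#' @param predicted,gold Data frames with columns `study_accession` and
#'   `pmid` (extra columns ignored), or character vectors of
#'   already-encoded keys.
#' @return One-row tibble `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_pairs <- function(predicted, gold) {
  as_keys <- function(x) {
    if (is.character(x)) return(unique(x))
    x <- as_tibble(x)
    unique(paste(x$study_accession, x$pmid, sep = "\t"))
  }
  p <- as_keys(predicted)
  g <- as_keys(gold)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}
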