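# Parsing the six SRA metadata object kinds from their XML files.
#
# Dialect (modeled on the public SRA schema, unknown elements ignored):
#   <STUDY_SET><STUDY accession="SRP...">...</STUDY>...</STUDY_SET> etc.
#   STUDY      DESCRIPTOR/STUDY_TITLE, DESCRIPTOR/STUDY_TYPE@existing_study_type
#   EXPERIMENT STUDY_REF@accession, DESIGN/SAMPLE_DESCRIPTOR@accession,
#              PLATFORM/*/INSTRUMENT_MODEL
#   RUN        EXPERIMENT_REF@accession
#   SAMPLE     SAMPLE_NAME/TAXON_ID, SAMPLE_NAME/SCIENTIFIC_NAME
#   ANALYSIS   STUDY_REF@accession
#   SUBMISSION STUDY_REF/EXPERIMENT_REF/RUN_REF/SAMPLE_REF/ANALYSIS_REF
#              children@accession (the ownership links: a submission owns the
#              objects it deposited)
#   any record: optional received="YYYY-MM-DD" attribute; *_LINKS blocks with
#              XREF_LINK (DB/ID as attributes or child elements); DB="pubmed"
#              entries become PubMed cross-references.

.sra_kinds <- c("submission", "study", "experiment", "run", "sample", "analysis")

.empty_refs <- function() tibble(kind = character(), accession = character())
.empty_xrefs <- function() tibble(db = character(), id = character())

#' Construct SRA metadata object records in code
#'
#' Builds one row of the tabular metadata-object representation that
#' [parse_sra_xml()] produces, convenient for assembling small corpora
#' programmatically.
#'
#' @param kind One of `"submission"`, `"study"`, `"experiment"`, `"run"`,
#'   `"sample"`, `"analysis"`.
#' @param accession Accession string; canonicalized via
#'   [normalize_accession()].
#' @param title,study_type,instrument_model,taxon_id,scientific_name Optional
#'   descriptive fields (each meaningful only for some kinds).
#' @param references A data frame with columns `kind` and `accession`, the
#'   typed links this record carries to other objects.
#' @param pubmed_refs Integer vector of cited PubMed identifiers.
#' @param xrefs A data frame with columns `db` and `id` of raw
#'   cross-reference links.
#' @param received_date Optional `Date` the record was received.
#' @return A one-row tibble of SRA object columns.
#' @examples
#' sra_object("study", "SRP000001", title = "A genome",
#'            study_type = "Whole Genome Sequencing")
#' @export
sra_object <- function(kind, accession, title = NA_character_,
                       study_type = NA_character_,
                       instrument_model = NA_character_,
                       taxon_id = NA_integer_,
                       scientific_name = NA_character_,
                       references = NULL, pubmed_refs = integer(),
                       xrefs = NULL, received_date = as.Date(NA)) {
  kind <- match.arg(kind, .sra_kinds)
  refs <- if (is.null(references)) .empty_refs() else
    as_tibble(references)[, c("kind", "accession")]
  xr <- if (is.null(xrefs)) .empty_xrefs() else as_tibble(xrefs)[, c("db", "id")]
  stopifnot(!anyDuplicated(pubmed_refs))
  tibble(
    kind = kind,
    accession = normalize_accession(accession),
    title = as.character(title),
    study_type = as.character(study_type),
    instrument_model = as.character(instrument_model),
    taxon_id = as.integer(taxon_id),
    scientific_name = as.character(scientific_name),
    references = list(refs),
    pubmed_refs = list(as.integer(unique(pubmed_refs))),
    xrefs = list(xr),
    received_date = as.Date(received_date)
  )
}

.empty_objects <- function() sra_object("study", "SRP000000")[0, ]

# first match by xpath, NA when absent
.xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else
    str_trim(xml2::xml_text(hit))
}

.xml_attr1 <- function(node, xpath, attr) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_attr(hit, attr)
}

# XREF_LINK entries accept DB/ID as attributes or as child elements
.collect_xrefs <- function(record) {
  links <- xml2::xml_find_all(record, ".//XREF_LINK")
  if (length(links) == 0) return(.empty_xrefs())
  db <- map_chr(links, function(l) {
    v <- xml2::xml_attr(l, "DB")
    if (is.na(v)) v <- .xml_text1(l, "./DB")
    v
  })
  id <- map_chr(links, function(l) {
    v <- xml2::xml_attr(l, "ID")
    if (is.na(v)) v <- .xml_text1(l, "./ID")
    v
  })
  tibble(db = db, id = id) |> filter(!is.na(.data$db), !is.na(.data$id))
}

.collect_references <- function(record, kind) {
  ref_kind_by_elem <- c(
    STUDY_REF = "study", EXPERIMENT_REF = "experiment", RUN_REF = "run",
    SAMPLE_REF = "sample", ANALYSIS_REF = "analysis"
  )
  refs <- list(.empty_refs())
  elems <- xml2::xml_find_all(
    record, "./STUDY_REF | ./EXPERIMENT_REF | ./RUN_REF | ./SAMPLE_REF | ./ANALYSIS_REF"
  )
  if (length(elems) > 0) {
    refs <- c(refs, list(tibble(
      kind = unname(ref_kind_by_elem[xml2::xml_name(elems)]),
      accession = xml2::xml_attr(elems, "accession")
    )))
  }
  if (kind == "experiment") {
    sd <- .xml_attr1(record, "./DESIGN/SAMPLE_DESCRIPTOR", "accession")
    if (!is.na(sd)) refs <- c(refs, list(tibble(kind = "sample", accession = sd)))
  }
  out <- bind_rows(refs) |> filter(!is.na(.data$accession))
  out$accession <- normalize_accession(out$accession)
  distinct(out)
}

.parse_record <- function(record, kind) {
  accession <- normalize_accession(xml2::xml_attr(record, "accession"))
  xrefs <- .collect_xrefs(record)
  pm <- xrefs$id[tolower(xrefs$db) == "pubmed"]
  pm <- unique(suppressWarnings(as.integer(pm)))
  pm <- pm[!is.na(pm) & pm > 0]
  title <- switch(kind,
    study = .xml_text1(record, "./DESCRIPTOR/STUDY_TITLE"),
    .xml_text1(record, "./TITLE")
  )
  received <- xml2::xml_attr(record, "received")
  sra_object(
    kind = kind,
    accession = accession,
    title = title,
    study_type = if (kind == "study")
      .xml_attr1(record, ".//STUDY_TYPE", "existing_study_type") else NA_character_,
    instrument_model = if (kind == "experiment")
      .xml_text1(record, "./PLATFORM//INSTRUMENT_MODEL") else NA_character_,
    taxon_id = if (kind == "sample") {
      tx <- .xml_text1(record, "./SAMPLE_NAME/TAXON_ID")
      if (is.na(tx)) NA_integer_ else as.integer(tx)
    } else NA_integer_,
    scientific_name = if (kind == "sample")
      .xml_text1(record, "./SAMPLE_NAME/SCIENTIFIC_NAME") else NA_character_,
    references = .collect_references(record, kind),
    pubmed_refs = pm,
    xrefs = xrefs,
    received_date = if (is.na(received)) as.Date(NA) else as.Date(received)
  )
}

#' Parse one SRA metadata XML document
#'
#' Reads a `*_SET` document of one of the six SRA object kinds and returns
#' one record per `SUBMISSION`/`STUDY`/`EXPERIMENT`/`RUN`/`SAMPLE`/`ANALYSIS`
#' element. Typed reference links between objects and PubMed
#' cross-references are captured; elements outside the dialect are ignored
#' silently so richer archive dumps still parse.
#'
#' @param x Path to an XML file, or a string of XML text.
#' @param kind The object kind the document holds.
#' @return A tibble of metadata objects (see [sra_object()] for the columns).
#'   Records lacking an `accession` attribute are skipped with a warning
#'   naming their element paths.
#' @export
parse_sra_xml <- function(x, kind) {
  kind <- match.arg(kind, .sra_kinds)
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) abort(paste0("malformed XML: ", conditionMessage(e)))
  )
  records <- xml2::xml_find_all(doc, paste0("/*/", toupper(kind)))
  if (length(records) == 0) return(.empty_objects())
  missing_acc <- map_lgl(records, function(r) is.na(xml2::xml_attr(r, "accession")))
  if (any(missing_acc)) {
    warn(paste0(
      "record missing accession attribute at: ",
      paste(map_chr(records[missing_acc], xml2::xml_path), collapse = ", ")
    ))
    records <- records[!missing_acc]
  }
  bind_rows(map(records, .parse_record, kind = kind))
}

#' Read a directory of SRA metadata XML files
#'
#' Expects up to six files named `submission.xml`, `study.xml`,
#' `experiment.xml`, `run.xml`, `sample.xml`, `analysis.xml`; absent files
#' are skipped.
#'
#' @param dir Directory path.
#' @return A tibble of all parsed metadata objects, all kinds combined.
#' @export
read_sra_dir <- function(dir) {
  parts <- map(.sra_kinds, function(k) {
    path <- file.path(dir, paste0(k, ".xml"))
    if (file.exists(path)) parse_sra_xml(path, k) else NULL
  })
  out <- bind_rows(compact(parts))
  if (nrow(out) == 0) .empty_objects() else out
}
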