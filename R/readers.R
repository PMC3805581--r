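# Readers for the literature-side input formats: MEDLINE flat records, plain
# full-text files, GEO SOFT series records, the MeSH ASCII descriptor file
# and the Disease Ontology OBO file.

# accept a file path or raw text; return lines
.as_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' The MeSH descriptor marking high-throughput sequencing articles
#'
#' @return Named character: the preferred heading under its unique
#'   identifier.
#' @export
hts_descriptor <- function() {
  c(D059014 = "High-Throughput Nucleotide Sequencing")
}

# "*Breast Neoplasms/genetics" -> "Breast Neoplasms"
.clean_mesh_heading <- function(x) {
  x <- sub("^\\*", "", str_trim(x))
  map_chr(strsplit(x, "/", fixed = TRUE), 1)
}

#' Read MEDLINE flat-format article records
#'
#' Parses the line-based MEDLINE format (`PMID- `, `TI  - `, `MH  - `
#' fields, records separated by blank lines). MeSH headings are cleaned of
#' major-topic asterisks and subheading qualifiers.
#'
#' @param x Path to a MEDLINE file, or its text.
#' @param hts_heading Heading name (or MeSH UI) whose presence flags an
#'   article as a high-throughput-sequencing article; defaults to the
#'   standard descriptor from [hts_descriptor()].
#' @return A tibble with one row per record: `pmid`, `title`,
#'   `mesh_headings` (list of character), `is_hts`.
#' @export
read_medline <- function(x, hts_heading = hts_descriptor()) {
  lines <- .as_lines(x)
  breaks <- cumsum(str_trim(lines) == "")
  chunks <- split(lines, breaks)
  recs <- compact(map(chunks, function(ch) {
    ch <- ch[str_trim(ch) != ""]
    if (length(ch) == 0) return(NULL)
    tag <- str_sub(ch, 1, 4)
    val <- str_trim(str_sub(ch, 7))
    pmid <- suppressWarnings(as.integer(val[tag == "PMID"][1]))
    if (is.na(pmid)) return(NULL)
    mh <- .clean_mesh_heading(val[tag == "MH  "])
    tibble(
      pmid = pmid,
      title = if (any(tag == "TI  ")) val[tag == "TI  "][1] else NA_character_,
      mesh_headings = list(mh)
    )
  }))
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble(pmid = integer(), title = character(),
                  mesh_headings = list())
  }
  targets <- tolower(c(hts_heading, names(hts_heading)))
  out$is_hts <- map_lgl(out$mesh_headings,
                        function(mh) any(tolower(mh) %in% targets))
  out
}

#' Read a directory of plain-text article full texts
#'
#' Files are named `<pmid>.txt`.
#'
#' @param dir Directory path.
#' @return Tibble `pmid`, `full_text`.
#' @export
read_fulltext_dir <- function(dir) {
  files <- list.files(dir, pattern = "^[0-9]+\\.txt$", full.names = TRUE)
  if (length(files) == 0) return(tibble(pmid = integer(), full_text = character()))
  tibble(
    pmid = as.integer(sub("\\.txt$", "", basename(files))),
    full_text = map_chr(files, function(f)
      paste(readr::read_lines(f), collapse = "\n"))
  ) |> arrange(.data$pmid)
}

#' Read an article corpus: MEDLINE records plus full texts
#'
#' @param medline Path to (or text of) the MEDLINE file.
#' @param fulltext_dir Optional directory of `<pmid>.txt` full texts;
#'   articles without a file get `NA` full text.
#' @param hts_heading Passed to [read_medline()].
#' @return Article tibble: `pmid`, `title`, `mesh_headings`, `is_hts`,
#'   `full_text`.
#' @export
read_article_corpus <- function(medline, fulltext_dir = NULL,
                                hts_heading = hts_descriptor()) {
  articles <- read_medline(medline, hts_heading = hts_heading)
  ft <- if (is.null(fulltext_dir)) tibble(pmid = integer(), full_text = character())
        else read_fulltext_dir(fulltext_dir)
  left_join(articles, ft, by = "pmid")
}

#' Read GEO SOFT-format series/dataset records
#'
#' Parses the line-oriented SOFT dialect: `^SERIES = GSE...` (or
#' `^DATASET = GDS...`) opens a record, `!Series_pubmed_id = N` attaches a
#' citing article, and SRA accessions are pulled out of
#' `!Series_relation = ...` lines (and any other attribute line) by
#' [extract_accessions()].
#'
#' @param x Path to a SOFT file, or its text.
#' @return Tibble with one row per GEO record: `accession`, `kind`
#'   (`geo_series`/`geo_dataset`), `pubmed_ids` (list of integer),
#'   `sra_relations` (list of character SRA accessions).
#' @export
read_geo_soft <- function(x) {
  lines <- .as_lines(x)
  empty <- tibble(accession = character(), kind = character(),
                  pubmed_ids = list(), sra_relations = list())
  starts <- grep("^\\^(SERIES|DATASET)\\s*=", lines)
  if (length(starts) == 0) return(empty)
  ends <- c(starts[-1] - 1, length(lines))
  recs <- map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    accession <- normalize_accession(str_trim(sub("^[^=]*=", "", block[1])))
    pm_lines <- grep("^!(Series|Dataset)_pubmed_id\\s*=", block, value = TRUE)
    pmids <- suppressWarnings(as.integer(str_trim(sub("^[^=]*=", "", pm_lines))))
    attr_lines <- grep("^!", block, value = TRUE)
    found <- extract_accessions(paste(attr_lines, collapse = "\n"))
    sra <- unique(found$accession[found$archive != "GEO"])
    tibble(
      accession = accession,
      kind = classify_accession(accession)$kind,
      pubmed_ids = list(unique(pmids[!is.na(pmids)])),
      sra_relations = list(sra)
    )
  })
  bind_rows(recs)
}

#' Parse the MeSH ASCII descriptor format
#'
#' Records are separated by `*NEWRECORD` lines; `MH = ` carries the
#' preferred heading, `UI = ` the unique identifier, and each `MN = ` line
#' one tree number (a descriptor may sit at several positions in the
#' hierarchy).
#'
#' @param x Path to a descriptor file (d2012.bin style), or its text.
#' @return Tibble `ui`, `name`, `tree_numbers` (list of character). Records
#'   carrying a heading but no UI are skipped with a warning; parsing
#'   continues.
#' @export
parse_mesh_ascii <- function(x) {
  lines <- .as_lines(x)
  empty <- tibble(ui = character(), name = character(), tree_numbers = list())
  starts <- which(str_trim(lines) == "*NEWRECORD")
  if (length(starts) == 0) return(empty)
  ends <- c(starts[-1] - 1, length(lines))
  bad <- character()
  recs <- compact(map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    field <- function(tag) {
      str_trim(sub(paste0("^", tag, " = "), "",
                   grep(paste0("^", tag, " = "), block, value = TRUE)))
    }
    mh <- field("MH")
    ui <- field("UI")
    if (length(ui) == 0) {
      if (length(mh) > 0) bad <<- c(bad, mh[1])
      return(NULL)
    }
    tibble(ui = ui[1], name = if (length(mh)) mh[1] else NA_character_,
           tree_numbers = list(field("MN")))
  }))
  if (length(bad) > 0) {
    warn(paste0("MeSH records without UI skipped: ", paste(bad, collapse = ", ")))
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0) empty else out
}

#' Parse a Disease Ontology OBO file
#'
#' Reads `[Term]` stanzas with `id:`, `name:`, `xref:` and `is_obsolete:`
#' lines. Cross-references are split into namespace and local id on the
#' first colon (`MSH:D001943`, `OMIM:114480`, ...). Obsolete terms are
#' flagged and excluded from downstream identifier mapping.
#'
#' @param x Path to an OBO file, or its text.
#' @return Tibble `doid`, `name`, `obsolete`, `xrefs` (list of tibbles
#'   `namespace`, `id`). Stanzas lacking an `id:` line are skipped with a
#'   warning.
#' @export
parse_do_obo <- function(x) {
  lines <- .as_lines(x)
  empty <- tibble(doid = character(), name = character(),
                  obsolete = logical(), xrefs = list())
  starts <- which(str_trim(lines) == "[Term]")
  if (length(starts) == 0) return(empty)
  ends <- c(starts[-1] - 1, length(lines))
  n_bad <- 0L
  recs <- compact(map2(starts, ends, function(s, e) {
    block <- str_trim(lines[s:e])
    block <- block[!grepl("^\\[", block)]
    field <- function(tag) {
      str_trim(sub(paste0("^", tag, ":"), "",
                   grep(paste0("^", tag, ":"), block, value = TRUE)))
    }
    id <- field("id")
    if (length(id) == 0) {
      n_bad <<- n_bad + 1L
      return(NULL)
    }
    xr <- field("xref")
    xr <- sub("\\s.*$", "", xr)  # drop trailing OBO comments
    parts <- stringr::str_split_fixed(xr, ":", 2)
    nm <- field("name")
    tibble(
      doid = id[1],
      name = if (length(nm)) nm[1] else NA_character_,
      obsolete = any(grepl("^is_obsolete:\\s*true", block)),
      xrefs = list(tibble(namespace = parts[, 1], id = parts[, 2]))
    )
  }))
  if (n_bad > 0) warn(paste0(n_bad, " OBO term stanza(s) without id skipped"))
  out <- bind_rows(recs)
  if (nrow(out) == 0) empty else out
}
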