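# Accession recognition: SRA (submission/study/experiment/run/sample/analysis
# across NCBI/EBI/DDBJ) and GEO (GSE series, GDS dataset) identifiers in
# tokens and free text.

# third prefix letter -> SRA object kind
.sra_kind_by_letter <- c(
  A = "submission", P = "study", X = "experiment",
  R = "run", S = "sample", Z = "analysis"
)
.archive_by_letter <- c(S = "NCBI", E = "EBI", D = "DDBJ")

# SRA accessions require >= 5 digits after the three-letter prefix (real
# accessions carry >= 6; 5 tolerates compact fixtures). GEO needs >= 1 digit.
.sra_core_pattern <- "[SED]R[APXRSZ][0-9]{5,}"
.geo_core_pattern <- "(?:GSE|GDS)[0-9]+"

#' Object kinds recognizable from an accession prefix
#'
#' @return Character vector of the six SRA object kinds plus the two GEO
#'   record kinds.
#' @export
accession_kinds <- function() {
  c(unname(.sra_kind_by_letter), "geo_series", "geo_dataset")
}

#' Classify an accession token
#'
#' Maps a bare token to its archive record kind and hosting archive from the
#' identifier prefix: `SRA`/`ERA`/`DRA` are submissions, `SRP`/`ERP`/`DRP`
#' studies, `SRX`/`ERX`/`DRX` experiments, `SRR`/`ERR`/`DRR` runs,
#' `SRS`/`ERS`/`DRS` samples, `SRZ`/`ERZ`/`DRZ` analyses; the first letter
#' distinguishes NCBI (`S`), EBI (`E`) and DDBJ (`D`). `GSE`/`GDS` prefixes
#' mark GEO series and datasets.
#'
#' @param token Character vector of candidate accession tokens.
#' @param case_insensitive Accept lower/mixed-case prefixes too. Off by
#'   default: prose abbreviations in running text are matched conservatively.
#' @return A tibble with one row per token: `accession`, `kind`, `archive`.
#'   Tokens that are not accessions get `NA` in `kind` and `archive`.
#' @examples
#' classify_accession(c("SRP000001", "DRR000001", "GSE5678", "XYZ123"))
#' @export
classify_accession <- function(token, case_insensitive = FALSE) {
  stopifnot(is.character(token))
  probe <- if (case_insensitive) toupper(token) else token
  sra_ok <- grepl(paste0("^", .sra_core_pattern, "$"), probe)
  geo_ok <- grepl(paste0("^", .geo_core_pattern, "$"), probe)
  kind <- archive <- rep(NA_character_, length(token))
  if (any(sra_ok)) {
    kind[sra_ok] <- unname(.sra_kind_by_letter[substr(probe[sra_ok], 3, 3)])
    archive[sra_ok] <- unname(.archive_by_letter[substr(probe[sra_ok], 1, 1)])
  }
  if (any(geo_ok)) {
    kind[geo_ok] <- ifelse(substr(probe[geo_ok], 2, 2) == "S",
                           "geo_series", "geo_dataset")
    archive[geo_ok] <- "GEO"
  }
  tibble(accession = token, kind = kind, archive = archive)
}

#' Extract SRA and GEO accessions from free text
#'
#' Scans text for accession mentions using regular-expression matching. A
#' match must be delimited by word boundaries: the character before and after
#' may not be a letter or digit (hyphens and dots count as boundaries, so a
#' trailing "SRP001234." is matched without the dot). Offsets are 0-based
#' with an exclusive end, the usual text-mining convention, so
#' `substr(text, start + 1, end)` recovers the match.
#'
#' @param text Character vector of documents to scan.
#' @param case_insensitive Also match lower/mixed-case accessions.
#' @return A tibble with one row per match in document order: `source` (index
#'   into `text`), `accession` (the matched substring), `kind`, `archive`,
#'   `start`, `end`. Repeated mentions of the same accession are all
#'   reported; matches never overlap.
#' @examples
#' extract_accessions("data deposited under SRP001234 and GSE999.")
#' @export
extract_accessions <- function(text, case_insensitive = FALSE) {
  stopifnot(is.character(text))
  pattern <- paste0(
    "(?<![A-Za-z0-9])(?:", .sra_core_pattern, "|", .geo_core_pattern,
    ")(?![A-Za-z0-9])"
  )
  if (case_insensitive) pattern <- paste0("(?i)", pattern)
  hits <- purrr::imap(text, function(doc, i) {
    m <- regmatches(doc, gregexpr(pattern, doc, perl = TRUE))[[1]]
    if (length(m) == 0) return(NULL)
    pos <- gregexpr(pattern, doc, perl = TRUE)[[1]]
    tibble(
      source = i,
      accession = m,
      start = as.integer(pos) - 1L,
      end = as.integer(pos) - 1L + attr(pos, "match.length")
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(
      source = integer(), accession = character(), kind = character(),
      archive = character(), start = integer(), end = integer()
    ))
  }
  cls <- classify_accession(out$accession, case_insensitive = case_insensitive)
  out$kind <- cls$kind
  out$archive <- cls$archive
  out[, c("source", "accession", "kind", "archive", "start", "end")]
}

#' Canonicalize an accession string
#'
#' Uppercases and strips a dot-version suffix (`"SRR000001.1"` becomes
#' `"SRR000001"`), the archive convention for citing versioned records.
#'
#' @param accession Character vector.
#' @return Character vector of canonical accessions.
#' @export
normalize_accession <- function(accession) {
  sub("\\.[0-9]+$", "", toupper(trimws(accession)))
}

# TRUE where accession parses as one of the six SRA kinds
is_sra_accession <- function(accession) {
  kind <- classify_accession(accession)$kind
  !is.na(kind) & !kind %in% c("geo_series", "geo_dataset")
}
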