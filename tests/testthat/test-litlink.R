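# fixture: chain SRR000101 -> SRX000050 -> SRP000010 (see helper)

empty_articles <- function() {
  tibble::tibble(pmid = integer(), title = character(),
                 mesh_headings = list(), is_hts = logical(),
                 full_text = character())
}

make_articles <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) return(empty_articles())
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(pmid = r$pmid, title = NA_character_,
                   mesh_headings = list(r$mh %||% character()),
                   is_hts = r$is_hts %||% TRUE,
                   full_text = r$text %||% NA_character_)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("metadata PubMed references become study-level links", {
  objs <- chain_objects()
  objs$pubmed_refs[[which(objs$accession == "SRP000010")]] <- 19015660L
  g <- build_accession_graph(objs)
  got <- pmids_from_metadata(objs, g)
  expect_equal(as.data.frame(got),
               data.frame(study_accession = "SRP000010", pmid = 19015660L,
                          provenance = "metadata_ref",
                          raw_accession = "SRP000010"),
               ignore_attr = TRUE)
  expect_equal(nrow(drop_log(got)), 0)
})

test_that("a run-level citation in the metadata is resolved to its study", {
  objs <- chain_objects()
  objs$pubmed_refs[[which(objs$accession == "SRR000101")]] <- 777L
  g <- build_accession_graph(objs)
  got <- pmids_from_metadata(objs, g)
  expect_equal(got$study_accession, "SRP000010")
  expect_equal(got$raw_accession, "SRR000101")
  # cross-check against the independent closure oracle
  expect_equal(got$study_accession, oracle_resolve(objs, "SRR000101"))
})

test_that("objects with no PubMed references produce no links", {
  objs <- chain_objects()
  g <- build_accession_graph(objs)
  expect_equal(nrow(pmids_from_metadata(objs, g)), 0)
})

test_that("full-text citations resolve and decoys are dropped with a log", {
  g <- build_accession_graph(chain_objects())
  arts <- make_articles(
    list(pmid = 111L, text = "Data are available under SRX000050."),
    list(pmid = 112L, text = "See SRR888888 and again SRR888888 for data.")
  )
  got <- pairs_from_fulltext(arts, g, hts_only = TRUE)
  expect_equal(as.data.frame(got[c("study_accession", "pmid")]),
               data.frame(study_accession = "SRP000010", pmid = 111L),
               ignore_attr = TRUE)
  log <- drop_log(got)
  # every dropped mention is logged, repeated mentions included
  expect_equal(nrow(log), 2)
  expect_equal(unique(log$accession), "SRR888888")
})

test_that("the sequencing-heading filter suppresses non-flagged articles", {
  g <- build_accession_graph(chain_objects())
  arts <- make_articles(
    list(pmid = 111L, text = "Deposited as SRX000050.", is_hts = FALSE))
  expect_equal(nrow(pairs_from_fulltext(arts, g, hts_only = TRUE)), 0)
  expect_equal(nrow(pairs_from_fulltext(arts, g, hts_only = FALSE)), 1)
})

geo_fixture <- function() {
  objs <- chain_objects()
  objs$title[objs$accession == "SRP000010"] <-
    "Chain study (raw data in GEO GSE200)"
  g <- build_accession_graph(objs)
  records <- tibble::tibble(
    accession = c("GSE100", "GSE200"),
    kind = "geo_series",
    pubmed_ids = list(222L, integer()),
    sra_relations = list("SRP000010", character())
  )
  list(objs = objs, g = g, records = records)
}

test_that("the GEO bridge is built from both directions and deduplicated", {
  fx <- geo_fixture()
  bridge <- build_geo_bridge(fx$records, fx$objs, fx$g)
  expect_equal(bridge$geo_accession, c("GSE100", "GSE200"))
  expect_equal(unique(bridge$study_accession), "SRP000010")
  expect_equal(bridge$source, c("from_geo_record", "from_sra_metadata"))

  # a pair discovered by both routes keeps the record-derived entry
  rec2 <- fx$records
  rec2$sra_relations[[2]] <- "SRP000010"
  bridge2 <- build_geo_bridge(rec2, fx$objs, fx$g)
  expect_equal(nrow(bridge2), 2)
  expect_equal(bridge2$source[bridge2$geo_accession == "GSE200"],
               "from_geo_record")
})

test_that("PMIDs cross the GEO bridge from records and from article text", {
  fx <- geo_fixture()
  bridge <- build_geo_bridge(fx$records, fx$objs, fx$g)
  no_articles <- empty_articles()
  got <- pairs_via_geo(fx$records, no_articles, bridge)
  expect_equal(as.data.frame(got),
               data.frame(study_accession = "SRP000010", pmid = 222L,
                          provenance = "geo_bridge", raw_accession = "GSE100"))
  arts <- make_articles(
    list(pmid = 333L, text = "Raw reads were obtained from GSE200."))
  got2 <- pairs_via_geo(fx$records, arts, bridge)
  expect_true(all(c(222L, 333L) %in% got2$pmid))
  # a GEO record with a PMID but no bridge entry contributes nothing
  lone <- tibble::tibble(accession = "GSE900", kind = "geo_series",
                         pubmed_ids = list(444L), sra_relations = list(character()))
  expect_equal(nrow(pairs_via_geo(lone, no_articles, bridge[0, ])), 0)
})

test_that("merging deduplicates on (study, pmid) with provenance priority", {
  a <- tibble::tibble(study_accession = "SRP000001", pmid = 99L,
                      provenance = "geo_bridge", raw_accession = "GSE1")
  b <- tibble::tibble(study_accession = "SRP000001", pmid = 99L,
                      provenance = "metadata_ref", raw_accession = "SRP000001")
  merged <- merge_publication_list(a, b)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$provenance, "metadata_ref")

  c1 <- tibble::tibble(study_accession = c("SRP000002", "SRP000003"),
                       pmid = c(1L, 2L), provenance = "fulltext_direct",
                       raw_accession = NA_character_)
  expect_equal(nrow(merge_publication_list(a, c1)), 3)
})

test_that("merging is idempotent and order-independent", {
  set.seed(7)
  mk <- function(n) tibble::tibble(
    study_accession = sprintf("SRP%06d", sample(5, n, replace = TRUE)),
    pmid = sample(10L, n, replace = TRUE),
    provenance = sample(c("metadata_ref", "fulltext_direct", "geo_bridge"),
                        n, replace = TRUE),
    raw_accession = NA_character_)
  for (rep in 1:10) {
    a <- mk(6); b <- mk(6)
    ab <- merge_publication_list(a, b)
    expect_equal(as.data.frame(merge_publication_list(ab, b)),
                 as.data.frame(ab))
    expect_equal(as.data.frame(merge_publication_list(b, a)),
                 as.data.frame(ab))
  }
})

test_that("pair evaluation follows the set formulas and boundary conventions", {
  pred <- tibble::tibble(study_accession = c("a", "b", "c", "d"),
                         pmid = 1L)
  gold <- tibble::tibble(study_accession = c("a", "b", "c", "e"),
                         pmid = 1L)
  got <- evaluate_pairs(pred, gold)
  expect_equal(got$precision, 0.75)
  expect_equal(got$recall, 0.75)

  same <- evaluate_pairs(gold, gold)
  expect_equal(c(same$precision, same$recall), c(1, 1))

  boundary <- evaluate_pairs(gold[0, ], gold[1, ])
  expect_true(is.na(boundary$precision))
  expect_equal(boundary$recall, 0)
})
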