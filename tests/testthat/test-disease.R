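mini_vocab <- function() {
  tibble::tibble(
    ui = c("D001943", "D011471", "D003866", "D012345", "D001921", "D099999"),
    name = c("Breast Neoplasms", "Prostatic Neoplasms", "Depressive Disorder",
             "Psychomotor Performance", "Brain", "Mixed Term"),
    tree_numbers = list(
      c("C04.588.180", "C17.800.090"),
      c("C04.588.945"),
      c("F03.600.300"),
      c("F02.463"),
      c("A08.186.211"),
      c("E05.598", "C23.550.291")
    )
  )
}

test_that("the disease filter accepts C and F03 branches with any-match", {
  v <- mini_vocab()
  expect_equal(is_disease_descriptor(v),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  # F03 must sit at a code boundary: F030-style codes do not leak in
  expect_false(is_disease_descriptor(list("F030.600")))
  expect_true(is_disease_descriptor(list("F03")))
})

test_that("the filter equals a brute-force prefix scan on random vocabularies", {
  set.seed(61)
  branches <- c("C04", "C10.228", "F03.600", "F02.463", "A08", "E05",
                "F030", "C23.550")
  for (rep in 1:20) {
    trees <- replicate(12, paste0(
      sample(branches, 1),
      if (runif(1) < 0.5) paste0(".", sample(100:999, 1)) else ""),
      simplify = TRUE)
    vocab <- split(trees, rep(1:4, each = 3))
    ours <- is_disease_descriptor(unname(vocab))
    brute <- vapply(vocab, function(tn) {
      any(substr(tn, 1, 1) == "C" & grepl("^C[0-9]", tn)) ||
        any(tn == "F03" | startsWith(tn, "F03."))
    }, logical(1))
    expect_equal(ours, unname(brute))
  }
})

test_that("annotations keep disease headings only and merge supporting PMIDs", {
  links <- tibble::tibble(
    study_accession = c("SRP000001", "SRP000001"),
    pmid = c(99L, 100L), provenance = "metadata_ref",
    raw_accession = NA_character_)
  articles <- tibble::tibble(
    pmid = c(99L, 100L), title = NA,
    mesh_headings = list(c("Breast Neoplasms", "Brain"),
                         c("Breast Neoplasms")),
    is_hts = TRUE, full_text = NA_character_)
  ann <- annotate_diseases(links, articles, mini_vocab())
  expect_equal(nrow(ann), 1)
  expect_equal(ann$ui, "D001943")
  expect_equal(ann$supporting_pmids[[1]], c(99L, 100L))
})

test_that("unknown headings are skipped with a warning, matching by UI works", {
  links <- tibble::tibble(study_accession = "SRP000001", pmid = 1L,
                          provenance = "manual", raw_accession = NA)
  articles <- tibble::tibble(
    pmid = 1L, title = NA,
    mesh_headings = list(c("D011471", "Completely Unknown Heading")),
    is_hts = TRUE, full_text = NA_character_)
  expect_warning(ann <- annotate_diseases(links, articles, mini_vocab()),
                 "Completely Unknown Heading")
  expect_equal(ann$ui, "D011471")
})

test_that("the frequency list counts distinct studies and conserves pairs", {
  ann <- tibble::tibble(
    study_accession = c("SRP000001", "SRP000002", "SRP000001"),
    ui = c("D001943", "D001943", "D011471"),
    name = c("Breast Neoplasms", "Breast Neoplasms", "Prostatic Neoplasms"),
    supporting_pmids = list(1L, 2L, 3L))
  freq <- disease_frequency(ann)
  expect_equal(freq$name, c("Breast Neoplasms", "Prostatic Neoplasms"))
  expect_equal(freq$n_projects, c(2L, 1L))
  expect_equal(sum(freq$n_projects),
               nrow(dplyr::distinct(ann, study_accession, ui)))
  expect_equal(nrow(disease_frequency(ann[0, ])), 0)
})

test_that("the tree materializes ancestor paths with distinct-study roll-ups", {
  vocab <- mini_vocab()
  ann <- tibble::tibble(study_accession = "SRP000001", ui = "D011471",
                        name = "Prostatic Neoplasms",
                        supporting_pmids = list(1L))
  tree <- build_disease_tree(ann, vocab)
  expect_equal(tree$tree_number, c("C04", "C04.588", "C04.588.945"))
  expect_equal(tree$rolled_count, c(1L, 1L, 1L))
  expect_equal(tree$own_count, c(0L, 0L, 1L))
  expect_equal(tree$ui[3], "D011471")

  # one study at two siblings still counts once at the parent
  ann2 <- tibble::tibble(
    study_accession = "SRP000001", ui = c("D001943", "D011471"),
    name = c("Breast Neoplasms", "Prostatic Neoplasms"),
    supporting_pmids = list(1L, 1L))
  tree2 <- build_disease_tree(ann2, vocab)
  expect_equal(tree2$rolled_count[tree2$tree_number == "C04.588"], 1L)
  nested <- tree_as_list(tree2)
  expect_equal(nested[[1]]$tree_number, "C04")
  expect_equal(nested[[1]]$children[[1]]$tree_number, "C04.588")
})

test_that("roll-ups equal brute-force subtree unions on random annotations", {
  set.seed(71)
  vocab <- mini_vocab()
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    ann <- tibble::tibble(
      study_accession = sprintf("SRP%06d", sample(4, n, replace = TRUE)),
      ui = sample(vocab$ui[is_disease_descriptor(vocab)], n, replace = TRUE)
    ) |> dplyr::distinct()
    ann$name <- vocab$name[match(ann$ui, vocab$ui)]
    ann$supporting_pmids <- list(1L)
    tree <- build_disease_tree(ann, vocab)
    placed <- ann |>
      dplyr::left_join(tidyr::unnest_longer(vocab, tree_numbers,
                                            values_to = "tree_number"),
                       by = "ui", relationship = "many-to-many")
    for (i in seq_len(nrow(tree))) {
      tn <- tree$tree_number[i]
      under <- placed$tree_number == tn | startsWith(placed$tree_number,
                                                     paste0(tn, "."))
      expect_equal(tree$rolled_count[i],
                   length(unique(placed$study_accession[under])), info = tn)
    }
  }
})

test_that("MeSH-to-OMIM mapping unions xrefs and keeps unlinked diseases empty", {
  terms <- parse_do_obo(paste(
    "[Term]", "id: DOID:1612", "name: breast cancer",
    "xref: MSH:D001943", "xref: OMIM:114480", "",
    "[Term]", "id: DOID:1324", "name: lung cancer",
    "xref: MSH:D008175", "",
    "[Term]", "id: DOID:9999", "name: breast cancer subtype",
    "xref: MSH:D001943", "xref: OMIM:604370", "",
    "[Term]", "id: DOID:0001", "name: gone",
    "xref: MSH:D001943", "xref: OMIM:999999", "is_obsolete: true",
    sep = "\n"))
  m <- mesh_to_omim(terms)
  expect_equal(m$omim_ids[[which(m$ui == "D001943")]], c(114480L, 604370L))
  expect_equal(m$omim_ids[[which(m$ui == "D008175")]], integer())
  # obsolete term's xref never surfaces
  expect_false(999999L %in% unlist(m$omim_ids))
})

test_that("adding ontology terms never removes an existing OMIM association", {
  base <- paste("[Term]", "id: DOID:1", "xref: MSH:D000001",
                "xref: OMIM:100100", sep = "\n")
  extra <- paste("[Term]", "id: DOID:2", "xref: MSH:D000002",
                 "xref: OMIM:200200", sep = "\n")
  m1 <- mesh_to_omim(parse_do_obo(base))
  m2 <- mesh_to_omim(parse_do_obo(paste(base, extra, sep = "\n")))
  for (i in seq_len(nrow(m1))) {
    j <- which(m2$ui == m1$ui[i])
    expect_true(all(m1$omim_ids[[i]] %in% m2$omim_ids[[j]]))
  }
})

test_that("Gendoo links interpolate the OMIM id and reject invalid ids", {
  expect_match(gendoo_url(114480), "114480", fixed = TRUE)
  expect_equal(gendoo_url(114480, template = "x/%s"), "x/114480")
  expect_error(gendoo_url(0), "positive")
})
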