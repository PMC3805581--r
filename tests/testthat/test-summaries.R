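make_submission <- function(i, kinds, accessions) {
  sra_object("submission", sprintf("SRA%06d", i),
             references = tibble::tibble(kind = kinds, accession = accessions))
}

test_that("identical submissions collapse to one counted pattern", {
  objs <- dplyr::bind_rows(
    sra_object("study", "SRP000001"),
    sra_object("experiment", "SRX000001"),
    sra_object("run", "SRR000001"),
    sra_object("sample", "SRS000001"),
    make_submission(1, c("study", "experiment", "run", "sample"),
                    c("SRP000001", "SRX000001", "SRR000001", "SRS000001")),
    make_submission(2, c("study", "experiment", "run", "sample"),
                    c("SRP000001", "SRX000001", "SRR000001", "SRS000001")),
    make_submission(3, c("study", "experiment", "run", "sample"),
                    c("SRP000001", "SRX000001", "SRR000001", "SRS000001"))
  )
  prof <- completeness_profiles(build_accession_graph(objs))
  expect_equal(nrow(prof), 1)
  expect_equal(prof$count, 3L)
  expect_true(all(unlist(prof[c("submission", "study", "experiment", "run", "sample")])))
  expect_false(prof$analysis)
})

test_that("profile counts partition submissions on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    objs <- random_objects(n_studies = 5)
    g <- build_accession_graph(objs)
    prof <- completeness_profiles(g)
    expect_equal(sum(prof$count), sum(objs$kind == "submission"))
    expect_false(is.unsorted(rev(prof$count)))
  }
  expect_equal(nrow(completeness_profiles(build_accession_graph(NULL))), 0)
})

test_that("project summaries aggregate platforms over member experiments", {
  objs <- dplyr::bind_rows(
    sra_object("study", "SRP000001", title = "Two-platform study"),
    sra_object("experiment", "SRX000001",
               instrument_model = "Illumina HiSeq 2000",
               references = tibble::tibble(kind = "study", accession = "SRP000001")),
    sra_object("experiment", "SRX000002",
               instrument_model = "Illumina Genome Analyzer II",
               references = tibble::tibble(kind = "study", accession = "SRP000001")),
    sra_object("study", "SRP000002", title = "Empty study")
  )
  p <- summarize_projects(build_accession_graph(objs))
  expect_equal(p$study_accession, c("SRP000001", "SRP000002"))
  expect_equal(p$platforms[[1]],
               c("Illumina Genome Analyzer II", "Illumina HiSeq 2000"))
  expect_equal(p$n_experiments, c(2L, 0L))
  expect_equal(p$platforms[[2]], character())
})

test_that("experiment counts per study match a brute-force recount", {
  set.seed(47)
  for (rep in 1:5) {
    objs <- random_objects(n_studies = 5)
    g <- build_accession_graph(objs)
    p <- summarize_projects(g)
    exps <- objs$accession[objs$kind == "experiment"]
    for (i in seq_len(nrow(p))) {
      expected <- sum(vapply(exps, function(e)
        p$study_accession[i] %in% oracle_resolve(objs, e), logical(1)))
      expect_equal(p$n_experiments[i], expected, info = p$study_accession[i])
    }
  }
})

test_that("facet tabulation counts a study once per category it carries", {
  projects <- tibble::tibble(
    study_accession = c("SRP000001", "SRP000002"),
    title = NA_character_, study_type = c("WGS", NA),
    platforms = list(character(), character()),
    taxa = list(
      tibble::tibble(taxon_id = 9606L, scientific_name = "Homo sapiens"),
      tibble::tibble(taxon_id = c(9606L, 10090L),
                     scientific_name = c("Homo sapiens", "Mus musculus"))
    ),
    n_experiments = c(1L, 1L), n_runs = c(1L, 1L),
    submissions = list(character(), character())
  )
  tab <- tabulate_by(projects, "taxon")
  expect_equal(tab$category, c("Homo sapiens", "Mus musculus"))
  expect_equal(tab$n_studies, c(2L, 1L))
  # total contributions exceed the number of studies: no deduplication
  expect_gt(sum(tab$n_studies), nrow(projects))
  expect_equal(tabulate_by(projects, "study_type")$n_studies, 1L)
  expect_equal(nrow(tabulate_by(projects[0, ], "platform")), 0)
  expect_error(tabulate_by(projects, "species"), "facet")
})

test_that("facet counts equal a brute-force per-category recount", {
  set.seed(53)
  objs <- random_objects(n_studies = 6)
  p <- summarize_projects(build_accession_graph(objs))
  tab <- tabulate_by(p, "study_type")
  incidences <- p |>
    dplyr::filter(!is.na(study_type)) |>
    dplyr::distinct(study_accession, study_type)
  expect_equal(sum(tab$n_studies), nrow(incidences))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n_studies[i],
                 sum(incidences$study_type == tab$category[i]))
  }
})
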