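small_config <- function(...) {
  corpus_config(n_studies = 8, n_articles = 12, seed = 17, ...)
}

test_that("generation is deterministic byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_corpus(small_config(decoy_rate = 1, geo_fraction = 0.25), d1)
  c2 <- generate_corpus(small_config(decoy_rate = 1, geo_fraction = 0.25), d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    a <- file.path(d1, f); b <- file.path(d2, f)
    expect_equal(readBin(a, "raw", file.size(a)),
                 readBin(b, "raw", file.size(b)), info = f)
  }
  expect_equal(c1$ground_truth, c2$ground_truth)
})

test_that("generated accessions are pattern-valid and decoys are graph-absent", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(small_config(decoy_rate = 2), d)
  objs <- read_sra_dir(corpus_paths(d)$sra)
  expect_true(all(!is.na(classify_accession(objs$accession)$kind)))
  decoys <- corp$ground_truth$decoy_mentions$accession
  expect_gt(length(decoys), 0)
  expect_true(all(!is.na(classify_accession(decoys)$kind)))
  expect_true(all(!decoys %in% objs$accession))
  # every planted pair's study really exists in the XML
  expect_true(all(corp$ground_truth$true_pairs$study_accession %in%
                    objs$accession[objs$kind == "study"]))
})

test_that("realized completeness patterns match the written metadata", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(small_config(), d)
  g <- build_accession_graph(read_sra_dir(corpus_paths(d)$sra))
  prof <- completeness_profiles(g)
  gt <- corp$ground_truth$per_submission_pattern
  expect_equal(sum(prof$count), nrow(gt))
  recount <- gt |>
    dplyr::count(submission_present, study_present, experiment_present,
                 run_present, sample_present, analysis_present,
                 name = "count") |>
    dplyr::arrange(dplyr::desc(count))
  expect_equal(sort(prof$count), sort(as.integer(recount$count)))
})

test_that("a clean corpus is recovered with perfect precision and recall", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(small_config(), d)
  res <- run_pipeline(d, file.path(d, "out"))
  ev <- evaluate_pairs(res$lit$links, corp$ground_truth$true_pairs)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(nrow(drop_log(res$lit$links)), 0)
})

test_that("decoy mentions are all dropped and logged, precision holds", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(small_config(decoy_rate = 2), d)
  res <- run_pipeline(d, file.path(d, "out"))
  ev <- evaluate_pairs(res$lit$links, corp$ground_truth$true_pairs)
  expect_equal(ev$precision, 1)
  expect_equal(nrow(drop_log(res$lit$links)),
               nrow(corp$ground_truth$decoy_mentions))
})

test_that("GEO-hosted studies are reachable only across the bridge", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(small_config(geo_fraction = 0.4), d)
  gt <- corp$ground_truth$true_pairs
  expect_gt(sum(gt$geo_only), 0)
  with_geo <- run_pipeline(d, file.path(d, "o1"))
  expect_equal(evaluate_pairs(with_geo$lit$links, gt)$recall, 1)
  without <- run_pipeline(d, file.path(d, "o2"), use_geo = FALSE)
  ev <- evaluate_pairs(without$lit$links, gt)
  expect_equal(ev$fp, 0L)
  expect_equal(ev$fn, sum(gt$geo_only))
  lost <- dplyr::anti_join(gt, tibble::as_tibble(without$lit$links),
                           by = c("study_accession", "pmid"))
  expect_true(all(lost$geo_only))
})

test_that("configuration invariants are enforced", {
  expect_error(corpus_config(completeness_mix = c("111110" = 0.5)), "0.5|sum")
  expect_error(corpus_config(geo_fraction = 1.5))
  expect_error(corpus_config(completeness_mix = c("011110" = 1)))
})
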