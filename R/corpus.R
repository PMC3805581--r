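# Deterministic synthetic-corpus generator: a self-consistent miniature of
# the archive snapshot the pipeline mines -- SRA metadata XML for the six
# object kinds, MEDLINE records with full texts, GEO SOFT series, a MeSH
# vocabulary slice and a Disease Ontology slice -- together with the ground
# truth describing every planted link, so every stage is testable offline.

#' Default disease descriptor pool for generated corpora
#'
#' A small slice of disease MeSH descriptors (with Disease Ontology OMIM
#' links where the ontology has them) covering neoplasms, infections and a
#' mental-disorders term, so both the C-branch and F03 filters and the
#' "no OMIM link" case are exercised.
#'
#' @return Tibble `ui`, `name`, `tree_numbers` (list), `omim` (integer,
#'   `NA` when the ontology holds no link).
#' @export
default_disease_pool <- function() {
  tibble(
    ui = c("D001943", "D011471", "D008175", "D008288", "D000544",
           "D003866", "D013203"),
    name = c("Breast Neoplasms", "Prostatic Neoplasms", "Lung Neoplasms",
             "Malaria", "Alzheimer Disease", "Depressive Disorder",
             "Staphylococcal Infections"),
    tree_numbers = list(
      c("C04.588.180", "C17.800.090.500"),
      c("C04.588.945.440.770", "C12.294.565.625"),
      c("C04.588.894.797.520", "C08.381.540"),
      c("C03.752.250", "C03.752.530"),
      c("C10.228.140.380.100"),
      c("F03.600.300"),
      c("C01.252.410.868")
    ),
    omim = c(114480L, 176807L, NA, 611162L, 104300L, 608516L, NA)
  )
}

#' Default non-disease descriptor pool for generated corpora
#'
#' Method, anatomy and organism headings (outside the C branch and F03),
#' including an F02 term guarding the F03 boundary.
#'
#' @return Tibble like [default_disease_pool()] without `omim`.
#' @export
default_nondisease_pool <- function() {
  tibble(
    ui = c("D017422", "D001921", "D051379", "D011588"),
    name = c("Sequence Analysis, DNA", "Brain", "Mice", "Psychomotor Performance"),
    tree_numbers = list(
      c("E05.393.760.700"),
      c("A08.186.211"),
      c("B01.050.150.900.649.313.992.635.505.500"),
      c("F02.808")
    )
  )
}

.default_taxa <- function() {
  tibble(
    taxon_id = c(9606L, 10090L, 7227L, 408172L, 4932L),
    scientific_name = c("Homo sapiens", "Mus musculus",
                        "Drosophila melanogaster", "marine metagenome",
                        "Saccharomyces cerevisiae")
  )
}

.default_platforms <- function() {
  c("Illumina HiSeq 2000", "Illumina Genome Analyzer II",
    "454 GS FLX Titanium", "AB SOLiD 4 System")
}

.default_study_types <- function() {
  c("Whole Genome Sequencing" = 0.45, "Transcriptome Analysis" = 0.25,
    "Metagenomics" = 0.15, "Epigenetics" = 0.15)
}

#' Configuration for a synthetic corpus
#'
#' All sizes, mixes and rates of the generated archive snapshot. Pattern
#' strings in `completeness_mix` are six `0`/`1` characters ordered
#' (submission, study, experiment, run, sample, analysis); the defaults
#' echo the archive's character, where most submissions deposit everything
#' except the optional analysis object and a tail of submissions is
#' incomplete.
#'
#' @param n_studies Number of studies (one submission each).
#' @param experiments_per_study,runs_per_experiment Inclusive integer
#'   ranges, sampled uniformly.
#' @param completeness_mix Named probabilities over pattern strings.
#' @param n_articles Number of citing articles.
#' @param citation_level_mix Probabilities over which accession level
#'   article full texts cite (`study`, `experiment`, `run`).
#' @param decoy_rate Expected number of decoy accession mentions per
#'   article: syntactically valid accessions absent from the archive, the
#'   false positives the resolution filter must drop.
#' @param geo_fraction Fraction of studies whose raw data lives in GEO:
#'   their articles cite the GEO series, never the SRA accession, so the
#'   pair is reachable only across the GEO bridge.
#' @param metadata_ref_rate Probability an article's PMID is also cited in
#'   the study metadata; `fulltext_cite_rate` the probability the article
#'   full text cites the accession (when neither fires, the metadata route
#'   is forced so every planted pair stays recoverable).
#' @param fulltext_cite_rate See `metadata_ref_rate`.
#' @param hts_heading_rate Fraction of articles carrying the
#'   high-throughput sequencing MeSH heading.
#' @param disease_pool,nondisease_pool Descriptor pools (see
#'   [default_disease_pool()]).
#' @param date_window Character vector of two dates bounding the received
#'   dates.
#' @param seed Integer seed; the same seed and config reproduce the corpus
#'   byte for byte.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_studies = 20,
                          experiments_per_study = c(1, 3),
                          runs_per_experiment = c(1, 2),
                          completeness_mix = c(
                            "111110" = 0.55, "111111" = 0.10,
                            "111100" = 0.10, "111010" = 0.10,
                            "110010" = 0.05, "110000" = 0.05,
                            "101110" = 0.05
                          ),
                          n_articles = 30,
                          citation_level_mix = c(study = 0.5,
                                                 experiment = 0.3,
                                                 run = 0.2),
                          decoy_rate = 0,
                          geo_fraction = 0,
                          metadata_ref_rate = 0.3,
                          fulltext_cite_rate = 0.9,
                          hts_heading_rate = 1.0,
                          disease_pool = default_disease_pool(),
                          nondisease_pool = default_nondisease_pool(),
                          date_window = c("2009-01-01", "2012-12-31"),
                          seed = 1L) {
  rates <- c(decoy_rate = decoy_rate, geo_fraction = geo_fraction,
             metadata_ref_rate = metadata_ref_rate,
             fulltext_cite_rate = fulltext_cite_rate,
             hts_heading_rate = hts_heading_rate)
  stopifnot(
    n_studies >= 1, n_articles >= 0,
    all(rates[-1] >= 0 & rates[-1] <= 1), decoy_rate >= 0,
    abs(sum(completeness_mix) - 1) < 1e-8,
    abs(sum(citation_level_mix) - 1) < 1e-8,
    all(grepl("^1[01]{5}$", names(completeness_mix)))
  )
  structure(
    list(
      n_studies = as.integer(n_studies),
      experiments_per_study = as.integer(experiments_per_study),
      runs_per_experiment = as.integer(runs_per_experiment),
      completeness_mix = completeness_mix,
      n_articles = as.integer(n_articles),
      citation_level_mix = citation_level_mix,
      decoy_rate = decoy_rate,
      geo_fraction = geo_fraction,
      metadata_ref_rate = metadata_ref_rate,
      fulltext_cite_rate = fulltext_cite_rate,
      hts_heading_rate = hts_heading_rate,
      disease_pool = disease_pool,
      nondisease_pool = nondisease_pool,
      date_window = as.Date(date_window),
      seed = as.integer(seed)
    ),
    class = "corpus_config"
  )
}

.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1, prob = prob)]

.range_draw <- function(range) {
  if (length(range) == 1) range else sample(seq(range[1], range[2]), 1)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic archive corpus with ground truth
#'
#' Writes, under `dir`, the full input layout the pipeline consumes:
#' `sra/{submission,study,experiment,run,sample,analysis}.xml`,
#' `articles/medline.txt` and `articles/fulltext/<pmid>.txt`,
#' `geo/series.soft`, `vocab/mesh.bin`, `vocab/do.obo`, and
#' `truth/*.tsv` mirrors of the returned ground truth. Identical config
#' and seed reproduce identical bytes.
#'
#' Decoy accessions are syntactically valid but absent from the metadata,
#' so they pass extraction and must be removed at resolution time, exactly
#' the situation the publication-list omission filter handles. Studies
#' assigned to GEO get a series record whose relation names the study; the
#' citing article mentions only the GEO accession.
#'
#' @param config A [corpus_config()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, an `sra_corpus` list: `dir`, `config`, and
#'   `ground_truth` with tibbles `true_pairs` (with per-route flags and
#'   `geo_only`), `articles`, `geo_bridge`, `disease`, `decoy_mentions`,
#'   `per_submission_pattern`.
#' @export
generate_corpus <- function(config = corpus_config(), dir) {
  stopifnot(inherits(config, "corpus_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create corpus directory: ", dir))
  for (sub in c("sra", "articles", "articles/fulltext", "geo", "vocab", "truth")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  taxa_pool <- .default_taxa()
  platforms <- .default_platforms()
  study_types <- .default_study_types()
  dates <- seq(config$date_window[1], config$date_window[2], by = "day")

  n <- config$n_studies
  exp_counter <- 0L
  run_counter <- 0L
  samp_counter <- 0L

  studies <- vector("list", n)
  for (i in seq_len(n)) {
    pattern <- .sample1(names(config$completeness_mix),
                        prob = unname(config$completeness_mix))
    bits <- as.logical(as.integer(strsplit(pattern, "")[[1]]))
    names(bits) <- .sra_kinds
    n_exp <- if (bits[["experiment"]]) .range_draw(config$experiments_per_study) else 0L
    exp_ids <- if (n_exp > 0) sprintf("SRX%06d", exp_counter + seq_len(n_exp)) else character()
    exp_counter <- exp_counter + n_exp
    runs <- map(seq_len(n_exp), function(j) {
      if (!bits[["run"]]) return(character())
      k <- .range_draw(config$runs_per_experiment)
      ids <- sprintf("SRR%06d", run_counter + seq_len(k))
      run_counter <<- run_counter + k
      ids
    })
    samples <- character()
    if (bits[["sample"]]) {
      k <- max(n_exp, 1L)
      samples <- sprintf("SRS%06d", samp_counter + seq_len(k))
      samp_counter <- samp_counter + k
    }
    taxon <- taxa_pool[sample.int(nrow(taxa_pool), 1), ]
    studies[[i]] <- list(
      study = sprintf("SRP%06d", i),
      submission = sprintf("SRA%06d", i),
      analysis = if (bits[["analysis"]]) sprintf("SRZ%06d", i) else character(),
      has_study = bits[["study"]],
      experiments = exp_ids,
      runs = runs,
      samples = samples,
      platform = map_chr(seq_len(n_exp), function(j) .sample1(platforms)),
      taxon = taxon,
      study_type = .sample1(names(study_types), prob = unname(study_types)),
      received = .sample1(dates),
      title = sprintf("Sequencing study %02d of %s", i, taxon$scientific_name),
      geo = NA_character_,
      pubmed = integer()
    )
  }

  resolvable <- which(map_lgl(studies, function(s) s$has_study))
  if (length(resolvable) == 0) abort("completeness mix produced no resolvable study")
  n_geo <- round(config$geo_fraction * length(resolvable))
  geo_idx <- if (n_geo > 0) sort(sample(resolvable, n_geo)) else integer()
  for (k in seq_along(geo_idx)) {
    i <- geo_idx[k]
    studies[[i]]$geo <- sprintf("GSE%d", 100 + k)
    if (stats::runif(1) < 0.5) {
      studies[[i]]$title <- paste0(studies[[i]]$title,
                                   " (raw data in GEO ", studies[[i]]$geo, ")")
    }
  }

  # ---- articles ----------------------------------------------------------
  hts_name <- unname(hts_descriptor())
  articles <- vector("list", config$n_articles)
  decoy_counter <- 0L
  decoy_rows <- list()
  for (a in seq_len(config$n_articles)) {
    pmid <- 20000000L + a
    i <- resolvable[(a - 1L) %% length(resolvable) + 1L]
    s <- studies[[i]]
    is_geo <- !is.na(s$geo)
    cite_accession <- NA_character_
    via_fulltext <- FALSE
    via_metadata <- FALSE
    via_geo <- FALSE
    if (is_geo) {
      via_geo <- TRUE
      cite_accession <- s$geo
    } else {
      levels_ok <- c(
        study = TRUE,
        experiment = length(s$experiments) > 0,
        run = any(lengths(s$runs) > 0)
      )
      mix <- config$citation_level_mix[names(levels_ok)[levels_ok]]
      level <- .sample1(names(mix), prob = unname(mix))
      cite_accession <- switch(level,
        study = s$study,
        experiment = .sample1(s$experiments),
        run = .sample1(unlist(s$runs))
      )
      via_fulltext <- stats::runif(1) < config$fulltext_cite_rate
      via_metadata <- stats::runif(1) < config$metadata_ref_rate
      if (!via_fulltext && !via_metadata) via_metadata <- TRUE
      if (via_metadata) {
        studies[[i]]$pubmed <- c(studies[[i]]$pubmed, pmid)
      }
    }
    n_decoys <- stats::rpois(1, config$decoy_rate)
    decoys <- character()
    if (n_decoys > 0) {
      decoys <- map_chr(seq_len(n_decoys), function(j) {
        decoy_counter <<- decoy_counter + 1L
        prefix <- if (decoy_counter %% 2 == 0) "SRR9" else "SRX9"
        sprintf("%s%05d", prefix, decoy_counter)
      })
      decoy_rows[[length(decoy_rows) + 1]] <-
        tibble(pmid = pmid, accession = decoys)
    }
    is_hts <- stats::runif(1) < config$hts_heading_rate
    n_dis <- sample(1:2, 1)
    dis <- config$disease_pool[sample.int(nrow(config$disease_pool), n_dis), ]
    nondis <- config$nondisease_pool[
      sample.int(nrow(config$nondisease_pool), 1), ]
    headings <- c(if (is_hts) hts_name, dis$name, nondis$name)
    articles[[a]] <- list(
      pmid = pmid, study = s$study, is_hts = is_hts,
      cite_accession = cite_accession,
      via_fulltext = via_fulltext, via_metadata = via_metadata,
      via_geo = via_geo, decoys = decoys, headings = headings,
      disease_uis = dis$ui,
      title = sprintf("Analysis of high-throughput sequencing dataset %02d", a)
    )
  }

  # ---- SRA XML -----------------------------------------------------------
  esc <- .xml_escape
  sub_lines <- c("<SUBMISSION_SET>")
  study_lines <- c("<STUDY_SET>")
  exp_lines <- c("<EXPERIMENT_SET>")
  run_lines <- c("<RUN_SET>")
  samp_lines <- c("<SAMPLE_SET>")
  ana_lines <- c("<ANALYSIS_SET>")
  for (s in studies) {
    owned <- c(
      if (s$has_study) sprintf('    <STUDY_REF accession="%s"/>', s$study),
      sprintf('    <EXPERIMENT_REF accession="%s"/>', s$experiments),
      sprintf('    <RUN_REF accession="%s"/>', unlist(s$runs)),
      sprintf('    <SAMPLE_REF accession="%s"/>', s$samples),
      sprintf('    <ANALYSIS_REF accession="%s"/>', s$analysis)
    )
    sub_lines <- c(sub_lines,
      sprintf('  <SUBMISSION accession="%s" received="%s">',
              s$submission, format(s$received)),
      owned,
      "  </SUBMISSION>")
    if (s$has_study) {
      pm <- unique(s$pubmed)
      links <- if (length(pm) > 0) c(
        "    <STUDY_LINKS>",
        sprintf('      <STUDY_LINK><XREF_LINK DB="pubmed" ID="%d"/></STUDY_LINK>', pm),
        "    </STUDY_LINKS>"
      ) else character()
      study_lines <- c(study_lines,
        sprintf('  <STUDY accession="%s" received="%s">', s$study, format(s$received)),
        "    <DESCRIPTOR>",
        sprintf("      <STUDY_TITLE>%s</STUDY_TITLE>", esc(s$title)),
        sprintf('      <STUDY_TYPE existing_study_type="%s"/>', esc(s$study_type)),
        "    </DESCRIPTOR>",
        links,
        "  </STUDY>")
    }
    for (j in seq_along(s$experiments)) {
      sd <- if (length(s$samples) >= j)
        sprintf('    <DESIGN><SAMPLE_DESCRIPTOR accession="%s"/></DESIGN>', s$samples[j])
      else character()
      exp_lines <- c(exp_lines,
        sprintf('  <EXPERIMENT accession="%s">', s$experiments[j]),
        sprintf("    <TITLE>Experiment %s</TITLE>", s$experiments[j]),
        sprintf('    <STUDY_REF accession="%s"/>', s$study),
        sd,
        "    <PLATFORM><ILLUMINA>",
        sprintf("      <INSTRUMENT_MODEL>%s</INSTRUMENT_MODEL>", esc(s$platform[j])),
        "    </ILLUMINA></PLATFORM>",
        "  </EXPERIMENT>")
      for (r in s$runs[[j]]) {
        run_lines <- c(run_lines,
          sprintf('  <RUN accession="%s">', r),
          sprintf('    <EXPERIMENT_REF accession="%s"/>', s$experiments[j]),
          "  </RUN>")
      }
    }
    for (sm in s$samples) {
      samp_lines <- c(samp_lines,
        sprintf('  <SAMPLE accession="%s">', sm),
        "    <SAMPLE_NAME>",
        sprintf("      <TAXON_ID>%d</TAXON_ID>", s$taxon$taxon_id),
        sprintf("      <SCIENTIFIC_NAME>%s</SCIENTIFIC_NAME>",
                esc(s$taxon$scientific_name)),
        "    </SAMPLE_NAME>",
        "  </SAMPLE>")
    }
    for (an in s$analysis) {
      ana_lines <- c(ana_lines,
        sprintf('  <ANALYSIS accession="%s">', an),
        sprintf('    <STUDY_REF accession="%s"/>', s$study),
        "  </ANALYSIS>")
    }
  }
  writeLines(c(sub_lines, "</SUBMISSION_SET>"), file.path(dir, "sra/submission.xml"))
  writeLines(c(study_lines, "</STUDY_SET>"), file.path(dir, "sra/study.xml"))
  writeLines(c(exp_lines, "</EXPERIMENT_SET>"), file.path(dir, "sra/experiment.xml"))
  writeLines(c(run_lines, "</RUN_SET>"), file.path(dir, "sra/run.xml"))
  writeLines(c(samp_lines, "</SAMPLE_SET>"), file.path(dir, "sra/sample.xml"))
  writeLines(c(ana_lines, "</ANALYSIS_SET>"), file.path(dir, "sra/analysis.xml"))

  # ---- articles: MEDLINE + full text ------------------------------------
  med_lines <- character()
  for (art in articles) {
    med_lines <- c(med_lines,
      sprintf("PMID- %d", art$pmid),
      sprintf("TI  - %s", art$title),
      sprintf("MH  - %s", art$headings),
      "")
    body <- c(
      art$title, "",
      paste("We sequenced libraries on a massively parallel platform and",
            "analysed the resulting reads."),
      if (art$via_geo)
        sprintf(paste("The data reported in this paper have been deposited in",
                      "the Gene Expression Omnibus under accession %s."),
                art$cite_accession)
      else if (art$via_fulltext)
        sprintf(paste("Sequence data have been deposited in the Sequence Read",
                      "Archive under accession %s."), art$cite_accession),
      if (length(art$decoys) > 0)
        sprintf("Additional datasets are available under accession %s.",
                art$decoys)
    )
    writeLines(body, file.path(dir, "articles/fulltext",
                               paste0(art$pmid, ".txt")))
  }
  writeLines(med_lines, file.path(dir, "articles/medline.txt"))

  # ---- GEO SOFT ----------------------------------------------------------
  soft <- character()
  for (k in seq_along(geo_idx)) {
    s <- studies[[geo_idx[k]]]
    pmids <- map_int(articles, function(a)
      if (a$via_geo && a$study == s$study) a$pmid else NA_integer_)
    pmids <- pmids[!is.na(pmids)]
    record_pm <- pmids[stats::runif(length(pmids)) < 0.5]
    soft <- c(soft,
      sprintf("^SERIES = %s", s$geo),
      sprintf("!Series_title = %s", s$title),
      sprintf("!Series_pubmed_id = %d", record_pm),
      sprintf("!Series_relation = SRA: https://www.ncbi.nlm.nih.gov/sra?term=%s",
              s$study))
  }
  writeLines(soft, file.path(dir, "geo/series.soft"))

  # ---- vocabularies ------------------------------------------------------
  vocab <- bind_rows(
    config$disease_pool |> select("ui", "name", "tree_numbers"),
    config$nondisease_pool |> select("ui", "name", "tree_numbers"),
    tibble(ui = names(hts_descriptor()), name = unname(hts_descriptor()),
           tree_numbers = list("E05.318.370.350"))
  )
  mesh_lines <- unlist(map(seq_len(nrow(vocab)), function(i) {
    c("*NEWRECORD",
      sprintf("MH = %s", vocab$name[i]),
      sprintf("MN = %s", vocab$tree_numbers[[i]]),
      sprintf("UI = %s", vocab$ui[i]),
      "")
  }))
  writeLines(mesh_lines, file.path(dir, "vocab/mesh.bin"))

  obo_lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(config$disease_pool))) {
    d <- config$disease_pool[i, ]
    obo_lines <- c(obo_lines,
      "[Term]",
      sprintf("id: DOID:%04d", i),
      sprintf("name: %s", tolower(d$name)),
      sprintf("xref: MSH:%s", d$ui),
      if (!is.na(d$omim)) sprintf("xref: OMIM:%d", d$omim),
      "")
  }
  # an obsolete term: its OMIM link must never surface in the mapping
  obo_lines <- c(obo_lines,
    "[Term]",
    sprintf("id: DOID:%04d", nrow(config$disease_pool) + 1L),
    "name: obsolete synthetic disease",
    sprintf("xref: MSH:%s", config$disease_pool$ui[1]),
    "xref: OMIM:999999",
    "is_obsolete: true",
    "")
  writeLines(obo_lines, file.path(dir, "vocab/do.obo"))

  # ---- ground truth ------------------------------------------------------
  art_tbl <- bind_rows(map(articles, function(a) {
    tibble(pmid = a$pmid, study_accession = a$study, is_hts = a$is_hts,
           cite_accession = a$cite_accession,
           via_metadata = a$via_metadata, via_fulltext = a$via_fulltext,
           via_geo = a$via_geo, disease_uis = list(a$disease_uis))
  }))
  true_pairs <- if (nrow(art_tbl) == 0) {
    tibble(study_accession = character(), pmid = integer(),
           via_metadata = logical(), via_fulltext = logical(),
           via_geo = logical(), geo_only = logical())
  } else {
    art_tbl |>
      group_by(.data$study_accession, .data$pmid) |>
      summarise(via_metadata = any(.data$via_metadata),
                via_fulltext = any(.data$via_fulltext),
                via_geo = any(.data$via_geo), .groups = "drop") |>
      mutate(geo_only = .data$via_geo & !.data$via_metadata &
               !.data$via_fulltext) |>
      arrange(.data$study_accession, .data$pmid)
  }
  geo_bridge_tbl <- bind_rows(map(studies[geo_idx], function(s)
    tibble(geo_accession = s$geo, study_accession = s$study)))
  if (length(geo_idx) == 0) {
    geo_bridge_tbl <- tibble(geo_accession = character(),
                             study_accession = character())
  }
  dis_lookup <- config$disease_pool |> select("ui", "name")
  disease_tbl <- if (nrow(art_tbl) == 0) {
    tibble(study_accession = character(), ui = character(),
           name = character(), supporting_pmids = list())
  } else {
    art_tbl |>
      select("study_accession", "pmid", "disease_uis") |>
      tidyr::unnest_longer("disease_uis", values_to = "ui") |>
      group_by(.data$study_accession, .data$ui) |>
      summarise(supporting_pmids = list(sort(unique(.data$pmid))),
                .groups = "drop") |>
      left_join(dis_lookup, by = "ui") |>
      select("study_accession", "ui", "name", "supporting_pmids") |>
      arrange(.data$study_accession, .data$ui)
  }
  decoy_tbl <- bind_rows(decoy_rows)
  if (nrow(decoy_tbl) == 0) decoy_tbl <- tibble(pmid = integer(),
                                                accession = character())
  pattern_tbl <- bind_rows(map(studies, function(s) {
    tibble(
      submission = s$submission,
      submission_present = TRUE,
      study_present = s$has_study,
      experiment_present = length(s$experiments) > 0,
      run_present = any(lengths(s$runs) > 0),
      sample_present = length(s$samples) > 0,
      analysis_present = length(s$analysis) > 0
    )
  }))

  readr::write_tsv(true_pairs, file.path(dir, "truth/true_pairs.tsv"))
  readr::write_tsv(geo_bridge_tbl, file.path(dir, "truth/geo_bridge.tsv"))
  readr::write_tsv(
    disease_tbl |>
      mutate(supporting_pmids = map_chr(.data$supporting_pmids,
                                        paste, collapse = ",")),
    file.path(dir, "truth/disease.tsv"))
  readr::write_tsv(decoy_tbl, file.path(dir, "truth/decoy_mentions.tsv"))
  readr::write_tsv(pattern_tbl, file.path(dir, "truth/patterns.tsv"))

  invisible(structure(
    list(
      dir = dir,
      config = config,
      ground_truth = list(
        true_pairs = true_pairs,
        articles = art_tbl,
        geo_bridge = geo_bridge_tbl,
        disease = disease_tbl,
        decoy_mentions = decoy_tbl,
        per_submission_pattern = pattern_tbl
      )
    ),
    class = "sra_corpus"
  ))
}

#' @export
print.sra_corpus <- function(x, ...) {
  cat("<sra_corpus> at ", x$dir, "\n",
      "  studies: ", x$config$n_studies,
      ", articles: ", x$config$n_articles,
      ", true pairs: ", nrow(x$ground_truth$true_pairs),
      ", decoy mentions: ", nrow(x$ground_truth$decoy_mentions), "\n",
      sep = "")
  invisible(x)
}
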