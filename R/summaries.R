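# Submission completeness patterns and per-study facet summaries.

#' Completeness patterns of submissions
#'
#' Not every submission deposits all six metadata object kinds (analysis
#' files in particular are optional). For each submission this tabulates
#' which kinds are present among the objects it owns, and counts submissions
#' per presence/absence pattern.
#'
#' @param graph An `accession_graph`.
#' @return A tibble with one row per observed pattern: logical columns
#'   `submission`, `study`, `experiment`, `run`, `sample`, `analysis` and a
#'   `count`, sorted by `count` descending. Counts partition the
#'   submissions: they sum to the number of distinct submission accessions.
#' @export
completeness_profiles <- function(graph) {
  stopifnot(inherits(graph, "accession_graph"))
  nodes <- graph$nodes
  subs <- nodes |> filter(.data$kind == "submission")
  if (nrow(subs) == 0) {
    return(tibble(
      submission = logical(), study = logical(), experiment = logical(),
      run = logical(), sample = logical(), analysis = logical(),
      count = integer()
    ))
  }
  kind_of <- stats::setNames(nodes$kind, nodes$accession)
  patterns <- map(subs$references, function(refs) {
    present <- unique(unname(kind_of[refs$accession]))
    stats::setNames(
      c(TRUE, .sra_kinds[-1] %in% present),
      .sra_kinds
    )
  })
  bind_rows(patterns) |>
    count(across(all_of(.sra_kinds)), name = "count") |>
    mutate(count = as.integer(.data$count)) |>
    arrange(desc(.data$count))
}

#' Per-study project summaries
#'
#' Aggregates each study's member objects into one project row: sequencing
#' platforms over member experiments, sample taxa over member samples, and
#' experiment/run counts, following the resolution topology. The result is
#' sortable by `n_experiments`, the conventional ordering for project lists.
#'
#' @param graph An `accession_graph`.
#' @return A tibble with one row per study: `study_accession`, `title`,
#'   `study_type`, `platforms` (list of character), `taxa` (list of tibbles
#'   `taxon_id`, `scientific_name`), `n_experiments`, `n_runs`,
#'   `submissions` (list of character), sorted by `n_experiments`
#'   descending then accession.
#' @export
summarize_projects <- function(graph) {
  stopifnot(inherits(graph, "accession_graph"))
  nodes <- graph$nodes
  studies <- nodes |> filter(.data$kind == "study")
  if (nrow(studies) == 0) {
    return(tibble(
      study_accession = character(), title = character(),
      study_type = character(), platforms = list(), taxa = list(),
      n_experiments = integer(), n_runs = integer(), submissions = list()
    ))
  }
  closure <- .study_closure(graph)
  node_info <- nodes |>
    select("accession", "instrument_model", "taxon_id", "scientific_name")
  members <- left_join(closure, node_info, by = "accession")
  per_study <- members |>
    group_by(.data$study_accession) |>
    summarise(
      platforms = list(sort(unique(
        .data$instrument_model[.data$kind == "experiment" &
                               !is.na(.data$instrument_model)]
      ))),
      taxa = list({
        sel <- .data$kind == "sample" & !is.na(.data$taxon_id)
        tid <- .data$taxon_id[sel]
        sn <- .data$scientific_name[sel]
        ord <- order(tid)
        distinct(tibble(taxon_id = tid[ord], scientific_name = sn[ord]))
      }),
      n_experiments = sum(.data$kind == "experiment"),
      n_runs = sum(.data$kind == "run"),
      submissions = list(sort(unique(.data$accession[.data$kind == "submission"]))),
      .groups = "drop"
    )
  studies |>
    select(study_accession = "accession", "title", "study_type") |>
    left_join(per_study, by = "study_accession") |>
    mutate(
      n_experiments = as.integer(.data$n_experiments),
      n_runs = as.integer(.data$n_runs)
    ) |>
    arrange(desc(.data$n_experiments), .data$study_accession)
}

#' Tabulate studies by a facet
#'
#' Counts studies per category of a facet. A study contributes once to
#' *each* category it carries — a study sequencing human and mouse samples
#' counts under both species — so the column total can exceed the number of
#' studies, as in multi-species archive statistics.
#'
#' @param projects Output of [summarize_projects()].
#' @param facet One of `"study_type"`, `"platform"`, `"taxon"`.
#' @return A tibble `category`, `n_studies`, sorted by count descending then
#'   category. Studies with no value for the facet contribute nothing.
#' @export
tabulate_by <- function(projects, facet = c("study_type", "platform", "taxon")) {
  if (length(facet) != 1 || !facet %in% c("study_type", "platform", "taxon")) {
    abort(paste0("unknown facet: ", paste(facet, collapse = ", ")))
  }
  empty <- tibble(category = character(), n_studies = integer())
  if (nrow(projects) == 0) return(empty)
  pairs <- switch(facet,
    study_type = projects |>
      filter(!is.na(.data$study_type)) |>
      dplyr::transmute(study_accession = .data$study_accession,
                       category = .data$study_type),
    platform = projects |>
      select("study_accession", "platforms") |>
      tidyr::unnest_longer("platforms", values_to = "category") |>
      filter(!is.na(.data$category)),
    taxon = projects |>
      select("study_accession", "taxa") |>
      tidyr::unnest("taxa") |>
      mutate(category = dplyr::coalesce(.data$scientific_name,
                                        paste0("taxon:", .data$taxon_id)))
  )
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    distinct(.data$study_accession, .data$category) |>
    count(.data$category, name = "n_studies") |>
    mutate(n_studies = as.integer(.data$n_studies)) |>
    arrange(desc(.data$n_studies), .data$category)
}
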